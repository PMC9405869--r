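test_that("block covariance has the requested structure", {
  cfg <- synthetic_config(n_nodes = 4, n_communities = 2,
                          within_community_corr = 0.6,
                          between_community_corr = 0.1,
                          target_node = 1, neighbourhood_size = 2)
  S <- build_population_covariance(cfg)
  expect_equal(diag(S), rep(1, 4))
  off <- sort(S[upper.tri(S)])
  expect_equal(off, c(0.1, 0.1, 0.1, 0.1, 0.6, 0.6))

  cfg0 <- synthetic_config(n_nodes = 5, n_communities = 1,
                           within_community_corr = 0,
                           between_community_corr = 0,
                           target_node = 1, neighbourhood_size = 2)
  expect_equal(build_population_covariance(cfg0), diag(5))
})

test_that("near-singular block matrices are repaired to positive definite", {
  cfg <- synthetic_config(n_nodes = 20, n_communities = 2,
                          within_community_corr = 0.9,
                          between_community_corr = 0.85,
                          target_node = 1, neighbourhood_size = 2,
                          effect_delta = 0.05)
  S <- build_population_covariance(cfg)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(diag(S), rep(1, 20))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(within_community_corr = 0.2,
                                between_community_corr = 0.5),
               "within_community_corr")
  expect_error(synthetic_config(effect_delta = 0.8,
                                within_community_corr = 0.3),
               "effect_delta")
  expect_error(synthetic_config(target_node = 500), "target_node")
  expect_error(synthetic_config(neighbourhood_size = 1),
               "neighbourhood_size")
})

test_that("identical config gives bit-identical panels", {
  cfg <- synthetic_config(n_subjects = 2, n_nodes = 12, n_timepoints = 30,
                          n_communities = 3, target_node = 2,
                          neighbourhood_size = 2, seed = 99)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$series, p2$series)
  p3 <- simulate_panel(synthetic_config(n_subjects = 2, n_nodes = 12,
                                        n_timepoints = 30,
                                        n_communities = 3, target_node = 2,
                                        neighbourhood_size = 2, seed = 100))
  expect_false(identical(p1$series$pre[[1]], p3$series$pre[[1]]))
})

test_that("null effect leaves pre and post correlation structure equal", {
  cfg <- synthetic_config(n_subjects = 1, n_nodes = 10, n_timepoints = 20000,
                          n_communities = 2, target_node = 2,
                          neighbourhood_size = 3, effect_delta = 0,
                          subject_noise_sd = 0, seed = 5)
  panel <- simulate_panel(cfg)
  r_pre <- pearson_connectivity(panel$series$pre[[1]])
  r_post <- pearson_connectivity(panel$series$post[[1]])
  # same population correlation: sample difference is Monte-Carlo noise
  expect_lt(max(abs(r_pre - r_post)), 0.05)
})

test_that("injected effect raises neighbourhood correlations by delta", {
  delta <- 0.2
  cfg <- synthetic_config(n_subjects = 1, n_nodes = 12, n_timepoints = 50000,
                          n_communities = 3, target_node = 1,
                          neighbourhood_size = 3, effect_delta = delta,
                          within_community_corr = 0.3,
                          subject_noise_sd = 0, seed = 17)
  panel <- simulate_panel(cfg)
  nbhd <- c(cfg$target_node, target_neighbourhood(cfg))
  r_pre <- pearson_connectivity(panel$series$pre[[1]])[nbhd, nbhd]
  r_post <- pearson_connectivity(panel$series$post[[1]])[nbhd, nbhd]
  diffs <- (r_post - r_pre)[upper.tri(r_pre)]
  expect_equal(mean(diffs), delta, tolerance = 0.05)
})

test_that("designated neighbourhood excludes the target and respects size", {
  cfg <- synthetic_config(n_nodes = 30, n_communities = 5, target_node = 7,
                          neighbourhood_size = 4)
  nb <- target_neighbourhood(cfg)
  expect_length(nb, 4)
  expect_false(7 %in% nb)
  memb <- community_membership(30, 5)
  expect_true(all(memb[nb] == memb[7]))
})

test_that("panels round-trip through TSV + manifest", {
  cfg <- synthetic_config(n_subjects = 2, n_nodes = 8, n_timepoints = 15,
                          n_communities = 2, target_node = 1,
                          neighbourhood_size = 2, seed = 3)
  panel <- simulate_panel(cfg)
  dir <- withr::local_tempdir()
  mpath <- write_panel(panel, dir)
  back <- read_panel(mpath)
  expect_equal(back$subjects, panel$subjects)
  expect_equal(back$series$pre[["sub-01"]], panel$series$pre[["sub-01"]],
               tolerance = 1e-12)
  expect_equal(back$series$post[["sub-02"]], panel$series$post[["sub-02"]],
               tolerance = 1e-12)
})

test_that("manifest with a missing session names the subject", {
  cfg <- synthetic_config(n_subjects = 2, n_nodes = 8, n_timepoints = 15,
                          n_communities = 2, target_node = 1,
                          neighbourhood_size = 2, seed = 3)
  dir <- withr::local_tempdir()
  mpath <- write_panel(simulate_panel(cfg), dir)
  man <- read.csv(mpath)
  man <- man[!(man$subject == "sub-02" & man$session == "post"), ]
  write.csv(man, mpath, row.names = FALSE)
  expect_error(read_panel(mpath), "sub-02")
})
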
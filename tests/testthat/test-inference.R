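test_that("paired t path reproduces hand-computed statistics", {
  # differences {1, 2, 0}: mean 1, SD 1 -> d_z = 1, t = sqrt(3), df = 2
  pre <- c(5, 5, 5)
  post <- c(6, 7, 5)
  res <- paired_compare(pre, post)
  expect_equal(res$test, "paired-t")
  expect_equal(res$effect_size_d, 1)
  expect_equal(res$statistic, sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$n_pairs, 3)
})

test_that("average-variance effect size uses the pooled session SD", {
  set.seed(9)
  pre <- rnorm(10)
  post <- pre + rnorm(10, 0.4)
  res <- paired_compare(pre, post, d_method = "average_variance")
  expect_equal(res$effect_size_d,
               mean(post - pre) / sqrt((var(pre) + var(post)) / 2))
  # p value and statistic are unaffected by the effect-size convention
  expect_equal(res$p_raw, paired_compare(pre, post)$p_raw)
})

test_that("Bonferroni correction multiplies and caps", {
  set.seed(3)
  pre <- rnorm(10)
  post <- pre + rnorm(10, 0.5)
  r1 <- paired_compare(pre, post, m = 1)
  r6 <- paired_compare(pre, post, m = 6)
  expect_equal(r6$p_corrected, min(1, 6 * r1$p_raw))
  expect_gte(r6$p_corrected, r6$p_raw)
  r_big <- paired_compare(pre, post, m = 10000)
  expect_equal(r_big$p_corrected, 1)
})

test_that("swapping pre and post negates t and d", {
  set.seed(6)
  pre <- rnorm(12)
  post <- pre + rnorm(12, 0.3)
  a <- paired_compare(pre, post)
  b <- paired_compare(post, pre)
  expect_equal(a$test, "paired-t")  # antisymmetry is a t-scale property
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$effect_size_d, -b$effect_size_d)
  expect_equal(a$p_raw, b$p_raw)
})

test_that("zero-variance differences raise an error", {
  expect_error(paired_compare(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "zero-variance")
  expect_error(paired_compare(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
})

test_that("heavy-tailed differences trigger the Wilcoxon fallback", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    pre <- rnorm(20)
    post <- pre + rcauchy(20)  # grossly non-normal differences
    res <- paired_compare(pre, post)
    hits <- hits + (res$test == "wilcoxon")
    if (res$test == "wilcoxon") expect_true(is.na(res$df))
  }
  expect_gte(hits, 15)
})

make_toy_metrics <- function(n_sub = 8, seed = 60, effect = 0) {
  # tiny panel -> metric table, cheap settings; strong communities and
  # moderate sparsity keep every thresholded network non-degenerate
  cfg <- synthetic_config(n_subjects = n_sub, n_nodes = 40,
                          n_timepoints = 80, n_communities = 4,
                          within_community_corr = 0.6,
                          target_node = 5, neighbourhood_size = 4,
                          effect_delta = effect, seed = seed)
  panel <- simulate_panel(cfg)
  compute_metric_curves(panel, target_node = 5,
                        grid = seq(0.14, 0.40, by = 0.02),
                        null_cfg = list(n_random = 2, n_swaps_per_edge = 3),
                        mod_cfg = list(restarts = 1), seed = seed)
}

toy_grid <- seq(0.14, 0.40, by = 0.02)

test_that("primary analysis returns the six-parameter family", {
  metrics <- make_toy_metrics()
  aucs <- auc_table(metrics, grid = toy_grid)
  hubs <- classify_hubs(metrics[metrics$parameter == "degree_centrality",
                                c("subject", "session", "threshold",
                                  "node", "value")])
  res <- run_primary_analysis(aucs, hubs)
  expect_equal(nrow(res), 6)
  expect_setequal(res$parameter,
                  c("global_efficiency", "modularity", "small_worldness",
                    "hubness", "nodal_efficiency", "local_efficiency"))
  expect_true(all(res$p_corrected >= res$p_raw))
  expect_true(all(res$p_raw >= 0 & res$p_corrected <= 1))
})

test_that("primary analysis reports subjects with a missing session", {
  metrics <- make_toy_metrics()
  aucs <- auc_table(metrics, grid = toy_grid)
  hubs <- classify_hubs(metrics[metrics$parameter == "degree_centrality",
                                c("subject", "session", "threshold",
                                  "node", "value")])
  aucs <- aucs[!(aucs$subject == "sub-03" & aucs$session == "post"), ]
  expect_error(run_primary_analysis(aucs, hubs), "sub-03")
})

test_that("stability subsets partition the grid and match primary stats", {
  metrics <- make_toy_metrics(seed = 61)
  stab <- stability_from_metrics(metrics, grid = toy_grid,
                                 parcellation = "toy")
  expect_equal(nrow(stab), 18)  # 6 parameters x 3 subsets
  aucs <- auc_table(metrics, grid = toy_grid)
  hubs <- classify_hubs(metrics[metrics$parameter == "degree_centrality",
                                c("subject", "session", "threshold",
                                  "node", "value")])
  primary <- run_primary_analysis(aucs, hubs, m = 1L)
  tot <- stab[stab$subset == "total", ]
  expect_equal(tot$statistic[match(primary$parameter, tot$parameter)],
               primary$statistic)
  expect_equal(tot$p_raw[match(primary$parameter, tot$parameter)],
               primary$p_raw)
  expect_equal(stab$non_comparable, stab$test == "wilcoxon")
})
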
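unit_path3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W
}

test_that("shortest paths follow 1/weight edge lengths", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(shortest_path_distances(tri),
               matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.5
  expect_equal(shortest_path_distances(W)[1, 3], 4)
  # two disconnected dyads
  W2 <- matrix(0, 4, 4)
  W2[1, 2] <- W2[2, 1] <- 1
  W2[3, 4] <- W2[4, 3] <- 1
  D <- shortest_path_distances(W2)
  expect_true(all(is.infinite(D[1:2, 3:4])))
})

test_that("efficiency measures reproduce closed-form toy values", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(global_efficiency(K4), 1)
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)
  expect_equal(global_efficiency(unit_path3()), 5 / 6)
  # star centre reaches all leaves directly
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(nodal_efficiency(star, 1), 1)
  expect_equal(nodal_efficiency(unit_path3(), 1), (1 + 1 / 2) / 2)
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(nodal_efficiency(iso, 3), 0)
  # local efficiency
  expect_equal(local_efficiency(K4, 2), 1)
  expect_equal(local_efficiency(star, 1), 0)
  # node whose neighbours form a unit 3-path
  W <- matrix(0, 4, 4)
  W[4, 1:3] <- 1
  W <- W + t(W)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  expect_equal(local_efficiency(W, 4), 5 / 6)  # neighbours form a 3-path
})

test_that("degree centrality is the node strength", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.25
  expect_equal(degree_centrality(W), c(0.75, 0.5, 0.25))
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(degree_centrality(K4), rep(3, 4))
})

test_that("modularity Q matches direct evaluation", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  expect_equal(modularity_q(W, rep(1:2, each = 4)), 0.5)
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(modularity_q(K5, rep(1, 5)), 0)
  opt <- optimize_modularity(W, restarts = 4, seed = 2)
  expect_gte(opt$Q, modularity_q(W, rep(1, 8)))
  expect_equal(opt$Q, 0.5)  # the component split is optimal here
  expect_error(optimize_modularity(matrix(0, 3, 3)), "no edges")
})

test_that("optimized modularity is deterministic given a seed", {
  set.seed(31)
  conn <- pearson_connectivity(matrix(rnorm(25 * 60), 25, 60))
  W <- proportional_threshold(conn, 0.2)$weights
  a <- optimize_modularity(W, restarts = 3, seed = 11)
  b <- optimize_modularity(W, restarts = 3, seed = 11)
  expect_identical(a, b)
})

test_that("Onnela clustering handles the canonical toy cases", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(weighted_clustering(tri), rep(1, 3))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(weighted_clustering(star)[1], 0)
  # triangle with weights 1, 1, 0.125: node joining the unit edges
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 1
  W[2, 3] <- W[3, 2] <- 0.125
  expect_equal(weighted_clustering(W)[1], 0.5)
})

test_that("rewired nulls preserve degrees and the weight multiset", {
  set.seed(5)
  conn <- pearson_connectivity(matrix(rnorm(20 * 80), 20, 80))
  W <- proportional_threshold(conn, 0.3)$weights
  nulls <- rewired_null(W, n_random = 5, n_swaps_per_edge = 10, seed = 9)
  for (Wn in nulls) {
    expect_equal(rowSums(Wn > 0), rowSums(W > 0))         # degree sequence
    expect_equal(sort(Wn[upper.tri(Wn) & Wn > 0]),
                 sort(W[upper.tri(W) & W > 0]))            # weight multiset
    expect_equal(sum(Wn), sum(W))                          # total weight
    expect_equal(Wn, t(Wn))
  }
  # same seed, same ensemble
  nulls2 <- rewired_null(W, n_random = 5, n_swaps_per_edge = 10, seed = 9)
  expect_identical(nulls, nulls2)
  # rewiring actually moves edges on a non-rigid graph
  expect_false(identical(nulls[[1]] > 0, W > 0))
})

test_that("complete graphs cannot be rewired", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  nulls <- rewired_null(K5, n_random = 3, n_swaps_per_edge = 20, seed = 1)
  for (Wn in nulls) expect_equal(Wn, K5)
  # a single-edge graph emits a warning and returns copies
  e1 <- matrix(0, 3, 3); e1[1, 2] <- e1[2, 1] <- 1
  expect_warning(nulls1 <- rewired_null(e1, n_random = 2), "too small")
  expect_equal(nulls1[[1]], e1)
})

test_that("small-worldness is 1 for complete graphs and detects lattices", {
  K6 <- matrix(0.7, 6, 6); diag(K6) <- 0
  expect_equal(small_worldness(K6, n_random = 5, seed = 3), 1)
  # ring lattice with neighbourhood 2: high clustering, long paths
  n <- 30
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in 1:2) {
    j <- ((i + d - 1) %% n) + 1
    W[i, j] <- W[j, i] <- 1
  }
  hits <- 0
  for (s in 1:10)
    hits <- hits + (small_worldness(W, n_random = 10,
                                    n_swaps_per_edge = 10, seed = s) > 1)
  expect_gte(hits, 9)
})

test_that("sigma is invariant under uniform weight rescaling", {
  set.seed(12)
  conn <- pearson_connectivity(matrix(rnorm(20 * 80), 20, 80))
  W <- proportional_threshold(conn, 0.3)$weights
  s1 <- small_worldness(W, n_random = 5, seed = 4)
  s2 <- small_worldness(W * 3.7, n_random = 5, seed = 4)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("adding an edge cannot decrease integration measures", {
  set.seed(21)
  for (rep in 1:10) {
    W <- random_connected_graph(6)
    # drop one existing edge to create W_minus
    ed <- which(upper.tri(W) & W > 0)
    pick <- sample(ed, 1)
    Wm <- W
    Wm[pick] <- 0
    Wm <- t(Wm); Wm[pick] <- 0; Wm <- t(Wm)
    expect_gte(global_efficiency(W) - global_efficiency(Wm), -1e-12)
    expect_true(all(degree_centrality(W) - degree_centrality(Wm) >= 0))
  }
})

test_that("efficiencies and clustering stay in [0, 1] for weights <= 1", {
  set.seed(22)
  for (rep in 1:10) {
    W <- random_connected_graph(7)
    expect_true(global_efficiency(W) >= 0 && global_efficiency(W) <= 1)
    expect_true(all(weighted_clustering(W) >= 0 &
                    weighted_clustering(W) <= 1))
    for (v in 1:7) {
      expect_true(local_efficiency(W, v) >= 0 &&
                  local_efficiency(W, v) <= 1)
      expect_true(nodal_efficiency(W, v) >= 0 &&
                  nodal_efficiency(W, v) <= 1)
    }
  }
})
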
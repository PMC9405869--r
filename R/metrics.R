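#' All-pairs shortest-path distances on a weighted network
#'
#' Edge lengths are the reciprocals of the (nonnegative) weights, so
#' strong connections are short; distances are exact shortest paths
#' and `+Inf` marks unreachable pairs.
#'
#' @param net A `"weighted_network"` or a symmetric nonnegative weight
#'   matrix with zero diagonal.
#' @return Symmetric matrix of shortest-path lengths, zero diagonal.
#' @export
shortest_path_distances <- function(net) {
  W <- as_weight_matrix(net)
  if (any(W < 0)) stop("weights must be nonnegative")
  apsp_distances_cpp(W)
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over all ordered node pairs, with
#' `1/Inf = 0` for disconnected pairs.  A network-integration measure:
#' 1 for a complete unit-weight graph, 0 for an edgeless one.
#'
#' @inheritParams shortest_path_distances
#' @param D Optional precomputed distance matrix (from
#'   [shortest_path_distances()]), to avoid recomputation.
#' @return Nonnegative scalar.
#' @export
global_efficiency <- function(net, D = NULL) {
  W <- as_weight_matrix(net)
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 nodes")
  if (is.null(D)) D <- apsp_distances_cpp(W)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' Mean inverse distance from one node to every other node; node-level
#' integration.
#'
#' @inheritParams global_efficiency
#' @param node Node index (1-based).
#' @return Nonnegative scalar.
#' @export
nodal_efficiency <- function(net, node, D = NULL) {
  W <- as_weight_matrix(net)
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 nodes")
  if (node < 1L || node > n) stop("node index out of range")
  if (is.null(D)) D <- apsp_distances_cpp(W)
  d <- D[node, -node]
  sum(ifelse(is.finite(d), 1 / d, 0)) / (n - 1)
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbours
#' (the node itself removed), with the original weights retained.
#' Measures node-level segregation / fault tolerance: how efficiently
#' the neighbourhood communicates if the node is disrupted.  Zero when
#' the node has fewer than 2 neighbours.
#'
#' @inheritParams nodal_efficiency
#' @return Scalar in `[0, 1]` when all weights are `<= 1`.
#' @export
local_efficiency <- function(net, node) {
  W <- as_weight_matrix(net)
  if (nrow(W) < 2L) stop("need at least 2 nodes")
  if (node < 1L || node > nrow(W)) stop("node index out of range")
  nb <- which(W[node, ] > 0)
  if (length(nb) < 2L) return(0)
  global_efficiency(W[nb, nb, drop = FALSE])
}

#' Degree centrality (node strength)
#'
#' The weighted degree of every node: the sum of its incident edge
#' weights.
#'
#' @inheritParams shortest_path_distances
#' @return Numeric vector of length `n`.
#' @export
degree_centrality <- function(net) {
  W <- as_weight_matrix(net)
  rowSums(W)
}

#' Evaluate modularity Q at a given partition
#'
#' Newman's weighted modularity
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) * [c_i == c_j]`
#' with `s` the node strengths and `2m` the total weight of both edge
#' directions.
#'
#' @inheritParams shortest_path_distances
#' @param membership Integer community label per node.
#' @return Scalar Q.
#' @export
modularity_q <- function(net, membership) {
  W <- as_weight_matrix(net)
  n <- nrow(W)
  if (length(membership) != n)
    stop("membership length must equal node count")
  s <- rowSums(W)
  two_m <- sum(s)
  if (two_m <= 0) stop("network has no edges")
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(W[idx, idx]) - sum(s[idx])^2 / two_m
  }
  q / two_m
}

#' Optimized modularity
#'
#' Finds a community partition by greedy multi-level (Louvain)
#' optimization and reports the best Q over `restarts` seeded runs,
#' which damps the optimizer's stochasticity.  Deterministic given
#' `seed`.
#'
#' @inheritParams shortest_path_distances
#' @param restarts Number of independent optimizer runs.
#' @param seed Integer seed.
#' @return List with `Q` (evaluated with [modularity_q()] at the best
#'   partition) and `membership`.
#' @export
optimize_modularity <- function(net, restarts = 10L, seed = 1L) {
  W <- as_weight_matrix(net)
  if (sum(W) <= 0) stop("network has no edges")
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  g <- igraph::make_graph(as.vector(t(idx)), n = nrow(W),
                          directed = FALSE)
  wts <- W[upper.tri(W) & W > 0]
  best_q <- -Inf
  best_m <- NULL
  set.seed(seed)
  for (r in seq_len(restarts)) {
    cl <- igraph::cluster_louvain(g, weights = wts)
    memb <- igraph::membership(cl)
    q <- modularity_q(W, memb)
    if (q > best_q) {
      best_q <- q
      best_m <- as.integer(memb)
    }
  }
  list(Q = best_q, membership = best_m)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node geometric-mean triangle intensity: with weights normalized
#' by the network maximum (`w_hat = w / max(w)`),
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w_hat_ij w_hat_ih
#' w_hat_jh)^(1/3)` over ordered neighbour pairs; 0 for nodes of degree
#' below 2.  Because of the max-normalization, uniform rescaling of all
#' weights leaves the coefficients unchanged.
#'
#' @inheritParams shortest_path_distances
#' @return Numeric vector of per-node coefficients in `[0, 1]`.
#' @export
weighted_clustering <- function(net) {
  W <- as_weight_matrix(net)
  as.numeric(onnela_clustering_cpp(W))
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all reachable ordered node pairs;
#' unreachable pairs are ignored.  `NA` if no pair is reachable.
#'
#' @inheritParams global_efficiency
#' @return Scalar.
#' @export
characteristic_path_length <- function(net, D = NULL) {
  W <- as_weight_matrix(net)
  if (is.null(D)) D <- apsp_distances_cpp(W)
  char_path_length_cpp(D)
}

#' Degree-preserving rewired null networks
#'
#' Generates an ensemble of randomized networks that preserve the
#' degree sequence through repeated double-edge swaps
#' (`n_swaps_per_edge` x edge-count attempted swaps per null); each
#' weight travels with its edge through the swaps, so the weight
#' multiset and total weight are preserved as well.  Deterministic given
#' `seed`.  If the graph has fewer than 2 edges no swap is possible:
#' unmodified copies are returned with a warning.
#'
#' @inheritParams shortest_path_distances
#' @param n_random Ensemble size.
#' @param n_swaps_per_edge Attempted swaps per edge.
#' @param seed Integer seed.
#' @return List of weight matrices.
#' @export
rewired_null <- function(net, n_random = 100L, n_swaps_per_edge = 10L,
                         seed = 1L) {
  W <- as_weight_matrix(net)
  if (n_random < 1L) stop("n_random must be >= 1")
  if (n_swaps_per_edge < 1L) stop("n_swaps_per_edge must be >= 1")
  m <- sum(W[upper.tri(W)] > 0)
  if (m < 2L) {
    warning("graph too small to swap (fewer than 2 edges); ",
            "returning unmodified copies")
    return(replicate(n_random, W, simplify = FALSE))
  }
  set.seed(seed)
  lapply(seq_len(n_random), function(k)
    rewire_weighted_cpp(W, as.integer(n_swaps_per_edge)))
}

# Largest connected component, derived from a distance matrix: nodes
# are in the same component iff their distance is finite.
largest_component_nodes <- function(D) {
  n <- nrow(D)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cur <- cur + 1L
      comp[is.finite(D[v, ])] <- cur
      comp[v] <- cur
    }
  }
  sizes <- tabulate(comp)
  which(comp == which.max(sizes))
}

#' Small-worldness
#'
#' `sigma = (C / C_rand) / (L / L_rand)`, where `C` is the mean Onnela
#' weighted clustering coefficient, `L` the characteristic path length
#' (mean finite distance), and `C_rand`, `L_rand` their means over an
#' ensemble of degree-preserving rewired nulls.  Values above 1 indicate
#' small-world organization.  Computed on the largest connected
#' component.  For a complete graph no double-edge swap can change the
#' edge set, so the nulls equal the input and `sigma = 1` exactly.
#'
#' @inheritParams rewired_null
#' @inheritParams global_efficiency
#' @return Positive scalar.
#' @export
small_worldness <- function(net, n_random = 100L, n_swaps_per_edge = 10L,
                            seed = 1L, D = NULL) {
  W <- as_weight_matrix(net)
  if (is.null(D)) D <- apsp_distances_cpp(W)
  lc <- largest_component_nodes(D)
  if (length(lc) < 3L) stop("largest component too small for sigma")
  Wl <- W[lc, lc, drop = FALSE]
  Dl <- D[lc, lc, drop = FALSE]
  C <- mean(weighted_clustering(Wl))
  L <- characteristic_path_length(Wl, D = Dl)
  m <- sum(Wl[upper.tri(Wl)] > 0)
  if (m < 2L)
    stop("largest component has fewer than 2 edges; sigma undefined")
  set.seed(seed)
  stats <- null_ensemble_stats_cpp(Wl, as.integer(n_random),
                                   as.integer(n_swaps_per_edge))
  Cr <- mean(stats[, 1])
  Lr <- mean(stats[, 2])
  if (!is.finite(Cr) || Cr <= 0 || !is.finite(Lr) || Lr <= 0)
    stop("degenerate null ensemble (zero clustering or path length)")
  (C / Cr) / (L / Lr)
}
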
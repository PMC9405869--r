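# Independent brute-force reference implementations used to validate
# the package's graph metrics on small graphs.  These deliberately share
# no code with the package: shortest paths are found by exhaustive
# enumeration of simple paths, modularity by direct evaluation of the
# definition (and, where used, exhaustive search over all partitions).

# exhaustive shortest paths: enumerate every simple path, length 1/w
oracle_distances <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dfs <- function(v, visited, len) {
      if (len < D[s, v]) D[s, v] <<- len
      for (u in which(W[v, ] > 0)) {
        if (!visited[u]) {
          dfs(u, replace(visited, u, TRUE), len + L[v, u])
        }
      }
    }
    dfs(s, replace(rep(FALSE, n), s, TRUE), 0)
  }
  D
}

oracle_global_efficiency <- function(W) {
  n <- nrow(W)
  D <- oracle_distances(W)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  }
  tot / (n * (n - 1))
}

oracle_nodal_efficiency <- function(W, node) {
  n <- nrow(W)
  D <- oracle_distances(W)
  tot <- 0
  for (j in seq_len(n)) {
    if (j != node && is.finite(D[node, j])) tot <- tot + 1 / D[node, j]
  }
  tot / (n - 1)
}

oracle_local_efficiency <- function(W, node) {
  nb <- which(W[node, ] > 0)
  if (length(nb) < 2) return(0)
  oracle_global_efficiency(W[nb, nb, drop = FALSE])
}

# Onnela clustering, literal triple loop over ordered neighbour pairs
oracle_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx <= 0) return(rep(0, n))
  A <- W / mx
  C <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h && W[j, h] > 0)
        s <- s + (A[i, j] * A[i, h] * A[j, h])^(1 / 3)
    }
    C[i] <- s / (k * (k - 1))
  }
  C
}

# modularity by direct evaluation of the definition over all node pairs
oracle_modularity_q <- function(W, membership) {
  n <- nrow(W)
  s <- rowSums(W)
  two_m <- sum(s)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j])
      q <- q + W[i, j] - s[i] * s[j] / two_m
  }
  q / two_m
}

# all set partitions of n elements as membership vectors (restricted
# growth strings); Bell(7) = 877 so exhaustive search is feasible
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) grow(c(prefix, v), max(mx, v))
  }
  grow(integer(0), 0L)
  out
}

oracle_best_modularity <- function(W) {
  parts <- all_partitions(nrow(W))
  max(vapply(parts, function(p) oracle_modularity_q(W, p), 0))
}

# random symmetric weighted graph; redraw until connected
random_connected_graph <- function(n, p_edge = 0.6) {
  repeat {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    on <- runif(sum(ut)) < p_edge
    w <- ifelse(on, runif(sum(ut), 0.1, 1), 0)
    W[ut] <- w
    W <- W + t(W)
    if (all(is.finite(oracle_distances(W)))) return(W)
  }
}
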
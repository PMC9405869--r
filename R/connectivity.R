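#' Pearson correlation connectivity matrix
#'
#' Edge weights are the Pearson correlations between every pair of node
#' time courses.  The diagonal is set to zero: self-connections carry no
#' information for the network measures downstream.
#'
#' @param series Numeric `nodes` x `timepoints` matrix (>= 3 timepoints).
#' @return Symmetric `nodes` x `nodes` matrix of correlations with zero
#'   diagonal, entries in `[-1, 1]`.
#' @export
#' @examples
#' pearson_connectivity(rbind(c(1, 2, 3, 4), c(1, 3, 2, 4)))
pearson_connectivity <- function(series) {
  series <- as.matrix(series)
  if (ncol(series) < 3L)
    stop("need at least 3 timepoints, got ", ncol(series))
  v <- apply(series, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance node signal at node index ",
         paste(which(v == 0), collapse = ", "))
  R <- cor(t(series))
  diag(R) <- 0
  dimnames(R) <- NULL
  (R + t(R)) / 2
}

#' Default proportional-threshold grid
#'
#' 18 edge-retention fractions from 6% to 40% of the strongest edges, in
#' 2% steps — a sparsity sweep wide enough that group comparisons do not
#' hinge on a single arbitrary threshold.
#'
#' @return Numeric vector `c(0.06, 0.08, ..., 0.40)` of length 18.
#' @export
default_threshold_grid <- function() {
  seq(3L, 20L, by = 1L) * 0.02
}

#' Subset a threshold grid into total / low / high sub-ranges
#'
#' Used by the stability analysis: `total` is the full grid, `low` the
#' thresholds up to and including 22%, `high` those from 24% upwards.
#'
#' @param grid Increasing vector of retention proportions.
#' @param split Boundary between the halves (`low` keeps values `<=
#'   split`); default 0.23 splits the default grid into 6–22% and
#'   24–40%.
#' @return Named list of grids: `total`, `low`, `high`.
#' @export
threshold_subsets <- function(grid = default_threshold_grid(),
                              split = 0.23) {
  list(total = grid,
       low = grid[grid <= split],
       high = grid[grid > split])
}

#' Proportional thresholding of a connectivity matrix
#'
#' Keeps the strongest `proportion` of all possible undirected edges:
#' negative and zero entries are discarded first, the remaining positive
#' edges are ranked by weight (descending), and the top
#' `floor(proportion * n * (n - 1) / 2)` are retained with their
#' original weights (no binarization).  Ties at the cutoff are broken by
#' ascending `(i, j)` node-index order, which makes the retained edge
#' sets nested across increasing proportions.
#'
#' If fewer positive edges exist than the retention quota, all positive
#' edges are kept and a warning reports the achieved density.
#'
#' @param conn Symmetric zero-diagonal correlation matrix (see
#'   [pearson_connectivity()]).
#' @param proportion Retention fraction in `(0, 1]`.
#' @return A list of class `"weighted_network"`: `weights` (symmetric
#'   nonnegative matrix, zero diagonal), `proportion`, and `n_edges`.
#' @export
proportional_threshold <- function(conn, proportion) {
  if (proportion <= 0 || proportion > 1)
    stop("proportion must be in (0, 1]")
  conn <- as.matrix(conn)
  n <- nrow(conn)
  ed <- edge_order_positive(conn)
  quota <- floor(proportion * n * (n - 1) / 2)
  n_keep <- min(quota, length(ed$w))
  if (length(ed$w) < quota)
    warning(sprintf(
      "only %d positive edges available for quota %d; achieved density %.4f",
      length(ed$w), quota, length(ed$w) / (n * (n - 1) / 2)))
  W <- matrix(0, n, n)
  if (n_keep > 0) {
    keep <- seq_len(n_keep)
    W[cbind(ed$i[keep], ed$j[keep])] <- ed$w[keep]
    W <- W + t(W)
  }
  structure(list(weights = W, proportion = proportion, n_edges = n_keep),
            class = "weighted_network")
}

# Positive upper-triangle edges ordered by descending weight, ties
# broken by ascending (i, j).  Shared by proportional_threshold() and
# threshold_sweep().
edge_order_positive <- function(conn) {
  n <- nrow(conn)
  ut <- which(upper.tri(conn))
  w <- conn[ut]
  pos <- w > 0
  ut <- ut[pos]
  w <- w[pos]
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  o <- order(-w, i, j)
  list(i = i[o], j = j[o], w = w[o])
}

#' Threshold sweep over a grid
#'
#' Applies [proportional_threshold()] at every grid proportion, ranking
#' the edges only once.  The returned networks are nested: each edge set
#' is a subset of the edge set at any larger proportion.
#'
#' @inheritParams proportional_threshold
#' @param grid Increasing vector of retention proportions.
#' @return List of `"weighted_network"` objects, one per grid value.
#' @export
threshold_sweep <- function(conn, grid = default_threshold_grid()) {
  conn <- as.matrix(conn)
  n <- nrow(conn)
  ed <- edge_order_positive(conn)
  lapply(grid, function(p) {
    quota <- floor(p * n * (n - 1) / 2)
    n_keep <- min(quota, length(ed$w))
    if (length(ed$w) < quota)
      warning(sprintf(
        "only %d positive edges available for quota %d at proportion %.2f",
        length(ed$w), quota, p))
    W <- matrix(0, n, n)
    if (n_keep > 0) {
      keep <- seq_len(n_keep)
      W[cbind(ed$i[keep], ed$j[keep])] <- ed$w[keep]
      W <- W + t(W)
    }
    structure(list(weights = W, proportion = p, n_edges = n_keep),
              class = "weighted_network")
  })
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> ", nrow(x$weights), " nodes, ", x$n_edges,
      " edges (proportion ", format(x$proportion), ")\n", sep = "")
  invisible(x)
}

# Accept either a weighted_network or a bare weight matrix.
as_weight_matrix <- function(net) {
  if (inherits(net, "weighted_network")) return(net$weights)
  W <- as.matrix(net)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  W
}
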
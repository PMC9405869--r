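#' Area under a metric-versus-threshold curve
#'
#' Collapses a per-threshold metric curve to a single scalar per
#' subject/session by trapezoidal integration of the metric value
#' against the retention proportion, so that group comparisons do not
#' depend on one arbitrary threshold.  Units: metric x proportion.
#'
#' @param values Metric value at each grid proportion.
#' @param grid Increasing vector of retention proportions, same length
#'   as `values` (length >= 2).
#' @return Scalar AUC.
#' @export
#' @examples
#' curve_auc(rep(2, 18), default_threshold_grid())  # 0.34 * 2
curve_auc <- function(values, grid = default_threshold_grid()) {
  if (length(values) != length(grid))
    stop("curve length (", length(values),
         ") does not match grid length (", length(grid), ")")
  if (length(grid) < 2L) stop("need at least 2 grid points")
  if (!all(is.finite(values))) stop("curve contains non-finite values")
  pracma::trapz(grid, values)
}

#' Classify hub nodes from pooled degree-centrality values
#'
#' Pools every degree-centrality value — all nodes, all thresholds, all
#' subjects, both sessions — into one distribution, computes its mean
#' and (sample) SD, and flags as hubs the observations whose value is at
#' least one SD above the mean.  The hub count per subject/session sums
#' the flags over nodes and thresholds.  No AUC collapse is involved.
#'
#' @param dc Data frame with columns `subject`, `session`, `threshold`,
#'   `node`, `value` (degree centrality).
#' @param n_sd Number of SDs above the mean for the cutoff (default 1).
#' @return A list of class `"hub_table"`: `pooled_mean`, `pooled_sd`,
#'   `cutoff`, `table` (the input with a logical `hub` column), and
#'   `counts` (per subject/session hub counts).
#' @export
#' @examples
#' dc <- data.frame(subject = "s1", session = "pre", threshold = 0.1,
#'                  node = 1:5, value = c(1, 1, 1, 1, 10))
#' classify_hubs(dc)$cutoff
classify_hubs <- function(dc, n_sd = 1) {
  need <- c("subject", "session", "threshold", "node", "value")
  if (!all(need %in% names(dc)))
    stop("dc must have columns: ", paste(need, collapse = ", "))
  if (nrow(dc) < 2L) stop("need at least 2 pooled values")
  mu <- mean(dc$value)
  sigma <- sd(dc$value)
  if (sigma == 0)
    stop("degenerate pooled degree-centrality distribution (SD = 0)")
  cutoff <- mu + n_sd * sigma
  dc$hub <- dc$value >= cutoff
  counts <- aggregate(hub ~ subject + session, data = dc, FUN = sum)
  names(counts)[names(counts) == "hub"] <- "n_hubs"
  structure(list(pooled_mean = mu, pooled_sd = sigma, cutoff = cutoff,
                 table = dc, counts = counts),
            class = "hub_table")
}

#' @export
print.hub_table <- function(x, ...) {
  cat("<hub_table> cutoff ", format(x$cutoff), " (mean ",
      format(x$pooled_mean), " + SD ", format(x$pooled_sd), "); ",
      sum(x$table$hub), " of ", nrow(x$table),
      " pooled observations flagged\n", sep = "")
  invisible(x)
}

#' AUC table from a tidy metrics table
#'
#' Integrates each (subject, session, parameter, node) curve over the
#' grid.  The metrics table is the tidy output of
#' [compute_metric_curves()]; degree-centrality rows are excluded (hubs
#' are classified from raw per-threshold values, not AUCs).
#'
#' @param metrics Data frame with columns `subject`, `session`,
#'   `threshold`, `parameter`, `node`, `value`.
#' @param grid Threshold grid the curves are aligned to.
#' @return Data frame with columns `subject`, `session`, `parameter`,
#'   `node`, `auc`.
#' @export
auc_table <- function(metrics, grid = default_threshold_grid()) {
  m <- metrics[metrics$parameter != "degree_centrality", , drop = FALSE]
  m <- m[m$threshold %in% grid, , drop = FALSE]
  key <- interaction(m$subject, m$session, m$parameter, m$node,
                     drop = TRUE)
  out <- lapply(split(m, key), function(d) {
    d <- d[order(d$threshold), , drop = FALSE]
    data.frame(subject = d$subject[1], session = d$session[1],
               parameter = d$parameter[1], node = d$node[1],
               auc = curve_auc(d$value, grid))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$parameter, out$subject, out$session), , drop = FALSE]
}
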
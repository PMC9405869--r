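#' Paired pre/post comparison of one parameter
#'
#' Tests the within-subject differences `post - pre`.  Normality of the
#' differences is checked with Shapiro-Wilk at `alpha_normality`; if not
#' rejected a dependent (paired) t test is used, otherwise the Wilcoxon
#' signed-rank test (exact p when `n <= 25` with no ties or zero
#' differences, normal approximation otherwise).  The reported effect
#' size is `d_z = mean(diff) / SD(diff)`.  Bonferroni correction
#' multiplies the raw p by `m` (capped at 1).
#'
#' @param pre,post Per-subject values, paired by position (length >= 3).
#' @param m Number of comparisons in the family for Bonferroni
#'   correction (use 1 for an uncorrected result).
#' @param parameter Optional parameter name carried into the result.
#' @param alpha_normality Significance level of the Shapiro-Wilk gate.
#' @param d_method `"dz"` (default) for `mean(diff) / SD(diff)`, or
#'   `"average_variance"` for `mean(diff)` standardized by the pooled SD
#'   of the pre and post values — the convention some published tables
#'   use.
#' @return One-row data frame: `parameter`, `test` (`"paired-t"` or
#'   `"wilcoxon"`), `statistic`, `df` (`NA` for Wilcoxon), `p_raw`,
#'   `p_corrected`, `effect_size_d`, `n_pairs`.
#' @export
#' @examples
#' paired_compare(c(1, 2, 3, 4, 6), c(2, 4, 3, 6, 7), m = 6)
paired_compare <- function(pre, post, m = 1L, parameter = NA_character_,
                           alpha_normality = 0.05,
                           d_method = c("dz", "average_variance")) {
  d_method <- match.arg(d_method)
  if (length(pre) != length(post))
    stop("pre and post must have equal length")
  n <- length(pre)
  if (n < 3L) stop("need at least 3 pairs")
  d <- post - pre
  sdd <- sd(d)
  if (sdd == 0)
    stop("zero-variance differences: t statistic and effect size undefined")
  d_z <- if (d_method == "dz") mean(d) / sdd
         else mean(d) / sqrt((stats::var(pre) + stats::var(post)) / 2)
  normal <- shapiro.test(d)$p.value >= alpha_normality
  if (normal) {
    tt <- t.test(post, pre, paired = TRUE)
    res <- data.frame(parameter = parameter, test = "paired-t",
                      statistic = unname(tt$statistic),
                      df = unname(tt$parameter),
                      p_raw = tt$p.value)
  } else {
    exact <- n <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
    wt <- suppressWarnings(wilcox.test(post, pre, paired = TRUE,
                                       exact = exact, correct = !exact))
    res <- data.frame(parameter = parameter, test = "wilcoxon",
                      statistic = unname(wt$statistic),
                      df = NA_real_,
                      p_raw = wt$p.value)
  }
  res$p_corrected <- min(1, m * res$p_raw)
  res$effect_size_d <- d_z
  res$n_pairs <- n
  res
}

# pull a named pre/post value pair per subject out of a long table,
# erroring if any subject lacks a session
paired_values <- function(tab, value_col) {
  subjects <- unique(tab$subject)
  for (ses in c("pre", "post")) {
    have <- tab$subject[tab$session == ses]
    missing <- setdiff(subjects, have)
    if (length(missing))
      stop("missing '", ses, "' session for subject(s): ",
           paste(missing, collapse = ", "))
  }
  pre <- tab[tab$session == "pre", ]
  post <- tab[tab$session == "post", ]
  list(pre = pre[[value_col]][match(subjects, pre$subject)],
       post = post[[value_col]][match(subjects, post$subject)])
}

#' Primary pre/post analysis of the six network parameters
#'
#' Runs [paired_compare()] for the six-parameter family — AUC-based
#' Global Efficiency, Modularity and Small-Worldness; count-based
#' Hubness; and AUC-based Nodal and Local Efficiency of the target node
#' — each Bonferroni-corrected with `m = 6`.
#'
#' @param aucs AUC table (see [auc_table()]).
#' @param hubs A `"hub_table"` (see [classify_hubs()]).
#' @param m Bonferroni family size (the six parameters).
#' @return Data frame with one [paired_compare()] row per parameter.
#' @export
run_primary_analysis <- function(aucs, hubs, m = 6L) {
  params <- c("global_efficiency", "modularity", "small_worldness",
              "nodal_efficiency", "local_efficiency")
  out <- lapply(params, function(p) {
    tab <- aucs[aucs$parameter == p, , drop = FALSE]
    if (!nrow(tab)) stop("no AUC rows for parameter ", p)
    pv <- paired_values(tab, "auc")
    paired_compare(pv$pre, pv$post, m = m, parameter = p)
  })
  hv <- paired_values(hubs$counts, "n_hubs")
  out[[length(out) + 1L]] <- paired_compare(hv$pre, hv$post, m = m,
                                            parameter = "hubness")
  res <- do.call(rbind, out)
  ord <- c("global_efficiency", "modularity", "small_worldness",
           "hubness", "nodal_efficiency", "local_efficiency")
  res <- res[match(ord, res$parameter), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Stability of the parameter comparisons across threshold sub-ranges
#'
#' Recomputes the six uncorrected paired comparisons on the total, low
#' and high halves of the threshold grid, from metric curves already
#' computed on the total grid (the AUCs and the pooled hub
#' classification are redone per subset).  Cells where the Wilcoxon
#' fallback fired are flagged `non_comparable`, since their statistics
#' are not on the t scale.
#'
#' @param metrics Tidy metrics table from [compute_metric_curves()].
#' @param grid The (total) threshold grid the metrics were computed on.
#' @param parcellation Label recorded in the output rows.
#' @param split Passed to [threshold_subsets()].
#' @return Data frame: `parcellation`, `subset`, `parameter`, `test`,
#'   `statistic`, `p_raw`, `effect_size_d`, `non_comparable`.
#' @export
stability_from_metrics <- function(metrics, grid = default_threshold_grid(),
                                   parcellation = "default",
                                   split = 0.23) {
  subsets <- threshold_subsets(grid, split = split)
  out <- lapply(names(subsets), function(sub_name) {
    sub_grid <- subsets[[sub_name]]
    if (!length(sub_grid)) stop("empty threshold subset: ", sub_name)
    msub <- metrics[metrics$threshold %in% sub_grid, , drop = FALSE]
    aucs <- auc_table(msub, grid = sub_grid)
    hubs <- classify_hubs(
      msub[msub$parameter == "degree_centrality",
           c("subject", "session", "threshold", "node", "value")])
    res <- run_primary_analysis(aucs, hubs, m = 1L)
    data.frame(parcellation = parcellation, subset = sub_name,
               parameter = res$parameter, test = res$test,
               statistic = res$statistic, p_raw = res$p_raw,
               effect_size_d = res$effect_size_d,
               non_comparable = res$test == "wilcoxon")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Stability analysis across parcellations and threshold sub-ranges
#'
#' For each parcellation specification, computes the metric curves on
#' its panel and the uncorrected paired statistics on the total, low
#' and high threshold sub-ranges.
#'
#' @param panels Named list of `"ts_panel"` objects, one per
#'   parcellation (names are the parcellation labels).
#' @param target_nodes Named integer vector: target-node index per
#'   parcellation.
#' @param grid Total threshold grid.
#' @param ... Passed to [compute_metric_curves()] (null-ensemble and
#'   modularity settings, seed).
#' @return Combined stability data frame (see
#'   [stability_from_metrics()]).
#' @export
run_stability_analysis <- function(panels, target_nodes,
                                   grid = default_threshold_grid(), ...) {
  stopifnot(length(panels) >= 1, !is.null(names(panels)),
            all(names(panels) %in% names(target_nodes)))
  out <- lapply(names(panels), function(pc) {
    metrics <- compute_metric_curves(panels[[pc]],
                                     target_node = target_nodes[[pc]],
                                     grid = grid, ...)
    stability_from_metrics(metrics, grid = grid, parcellation = pc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
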
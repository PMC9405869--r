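#' Replicate-cohort operating characteristics of the paired analysis
#'
#' Simulates `n_cohorts` independent synthetic cohorts from
#' `base_config` (each with its own derived seed), runs the pipeline's
#' paired pre/post comparison for the requested parameters on each, and
#' returns the per-cohort test results.  With `effect_delta = 0` this
#' estimates the type-I error rate of the analysis; with a positive
#' injected effect it estimates power.
#'
#' Only the requested parameters are computed, so e.g. a pure
#' local-efficiency study skips the (expensive) null ensembles and
#' modularity optimization entirely.
#'
#' @param base_config A [synthetic_config()]; its `seed` is replaced by
#'   a per-cohort seed derived from `seed`.
#' @param n_cohorts Number of independent cohorts.
#' @param parameters Subset of `c("global_efficiency", "modularity",
#'   "small_worldness", "hubness", "nodal_efficiency",
#'   "local_efficiency")`.
#' @param grid Threshold grid.
#' @param null_cfg,mod_cfg Small-worldness null-ensemble and modularity
#'   settings (see [compute_metric_curves()]).
#' @param m Bonferroni family size applied to each comparison.
#' @param seed Master seed for the cohort stream.
#' @return Data frame with columns `cohort`, `parameter`, `test`,
#'   `statistic`, `p_raw`, `p_corrected`, `effect_size_d`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_subjects = 6, n_nodes = 20, n_timepoints = 60,
#'                         n_communities = 4, target_node = 3,
#'                         neighbourhood_size = 3, effect_delta = 0)
#' replicate_cohort_tests(cfg, n_cohorts = 2,
#'                        parameters = "local_efficiency",
#'                        grid = c(0.1, 0.2, 0.3))
replicate_cohort_tests <- function(base_config,
                                   n_cohorts,
                                   parameters = "local_efficiency",
                                   grid = default_threshold_grid(),
                                   null_cfg = list(n_random = 100L,
                                                   n_swaps_per_edge = 10L),
                                   mod_cfg = list(restarts = 10L),
                                   m = 6L,
                                   seed = 1L) {
  all_params <- c("global_efficiency", "modularity", "small_worldness",
                  "hubness", "nodal_efficiency", "local_efficiency")
  parameters <- match.arg(parameters, all_params, several.ok = TRUE)
  metric_params <- setdiff(parameters, "hubness")
  if ("hubness" %in% parameters)
    metric_params <- union(metric_params, "degree_centrality")
  out <- vector("list", n_cohorts)
  for (cc in seq_len(n_cohorts)) {
    cfg <- base_config
    cfg$seed <- derive_seed(seed, cc)
    panel <- simulate_panel(cfg)
    metrics <- compute_metric_curves(panel,
                                     target_node = cfg$target_node,
                                     grid = grid,
                                     parameters = metric_params,
                                     null_cfg = null_cfg,
                                     mod_cfg = mod_cfg,
                                     seed = derive_seed(seed, 100000L + cc))
    res <- list()
    auc_params <- setdiff(parameters, "hubness")
    if (length(auc_params)) {
      aucs <- auc_table(metrics, grid = grid)
      for (p in auc_params) {
        pv <- paired_values(aucs[aucs$parameter == p, , drop = FALSE],
                            "auc")
        res[[p]] <- paired_compare(pv$pre, pv$post, m = m, parameter = p)
      }
    }
    if ("hubness" %in% parameters) {
      hubs <- classify_hubs(
        metrics[metrics$parameter == "degree_centrality",
                c("subject", "session", "threshold", "node", "value")])
      hv <- paired_values(hubs$counts, "n_hubs")
      res$hubness <- paired_compare(hv$pre, hv$post, m = m,
                                    parameter = "hubness")
    }
    res <- do.call(rbind, res)
    res$cohort <- cc
    out[[cc]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("cohort", "parameter", "test", "statistic", "p_raw",
        "p_corrected", "effect_size_d")]
}

#' Rejection rates from a replicate-cohort study
#'
#' @param results Output of [replicate_cohort_tests()].
#' @param alpha Significance level.
#' @param corrected Use `p_corrected` (TRUE) or `p_raw` (FALSE).
#' @return Data frame with `parameter`, `n_cohorts`, `rejection_rate`.
#' @export
rejection_rates <- function(results, alpha = 0.05, corrected = FALSE) {
  p <- if (corrected) results$p_corrected else results$p_raw
  agg <- aggregate(list(rejection_rate = p < alpha),
                   by = list(parameter = results$parameter), FUN = mean)
  n <- aggregate(list(n_cohorts = p),
                 by = list(parameter = results$parameter), FUN = length)
  merge(n, agg, by = "parameter")
}
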
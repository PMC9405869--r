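#' Per-threshold metric curves for a whole panel
#'
#' For every (subject, session), builds the Pearson connectivity
#' matrix, sweeps the proportional-threshold grid, and computes the
#' requested parameters on each thresholded network:
#' `global_efficiency`, `modularity` (Q at the optimized partition),
#' `small_worldness`, `degree_centrality` (every node), and
#' `nodal_efficiency` / `local_efficiency` of the target node.
#' Metrics other than small-worldness are computed on the network as
#' thresholded, including isolated nodes; small-worldness is computed
#' on the largest connected component.
#'
#' @param panel A `"ts_panel"`.
#' @param target_node Node index for the nodal/local parameters.
#' @param grid Threshold grid.
#' @param parameters Character subset of the parameters to compute
#'   (default: all six).
#' @param null_cfg List with `n_random`, `n_swaps_per_edge` for the
#'   small-worldness null ensemble.
#' @param mod_cfg List with `restarts` for the modularity optimizer.
#' @param seed Integer seed driving the null ensembles and optimizer
#'   restarts (one derived seed per network, so results do not depend
#'   on evaluation order).
#' @return Tidy data frame: `subject`, `session`, `threshold`,
#'   `parameter`, `node` (`""` for global parameters), `value`.
#' @export
compute_metric_curves <- function(panel, target_node,
                                  grid = default_threshold_grid(),
                                  parameters = c("global_efficiency",
                                                 "modularity",
                                                 "small_worldness",
                                                 "degree_centrality",
                                                 "nodal_efficiency",
                                                 "local_efficiency"),
                                  null_cfg = list(n_random = 100L,
                                                  n_swaps_per_edge = 10L),
                                  mod_cfg = list(restarts = 10L),
                                  seed = 1L) {
  stopifnot(inherits(panel, "ts_panel"))
  parameters <- match.arg(parameters, several.ok = TRUE)
  if (target_node < 1L || target_node > panel$n_nodes)
    stop("target_node out of range for this panel")
  rows <- vector("list", 0L)
  net_id <- 0L
  for (ses in panel$sessions) {
    for (sub in panel$subjects) {
      conn <- pearson_connectivity(panel$series[[ses]][[sub]])
      nets <- threshold_sweep(conn, grid)
      for (k in seq_along(nets)) {
        net_id <- net_id + 1L
        vals <- network_parameter_values(
          nets[[k]], target_node, parameters, null_cfg, mod_cfg,
          seed = derive_seed(seed, net_id))
        rows[[net_id]] <- data.frame(
          subject = sub, session = ses, threshold = grid[k],
          parameter = vals$parameter, node = vals$node,
          value = vals$value)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# small-integer seed stream that stays inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

# Small null ensembles on a near-tree largest component can come back
# with zero clustering in every null, leaving sigma's normalizer
# undefined.  Enlarge the ensemble (doubling, up to 3 times) before
# giving up: as soon as one null recovers a triangle the normalizer is
# positive.  Non-degenerate networks are unaffected (first attempt uses
# the caller's ensemble size and seed).
sigma_with_retry <- function(W, null_cfg, seed, D = NULL) {
  n_random <- null_cfg$n_random
  for (attempt in 1:4) {
    s <- tryCatch(
      small_worldness(W, n_random = n_random,
                      n_swaps_per_edge = null_cfg$n_swaps_per_edge,
                      seed = if (attempt == 1) seed
                             else derive_seed(seed, 7000L + attempt),
                      D = D),
      error = function(e) {
        if (grepl("degenerate null", conditionMessage(e))) NULL
        else stop(e)
      })
    if (!is.null(s)) return(s)
    n_random <- 2L * n_random
  }
  stop("small-worldness null ensemble degenerate even after enlarging ",
       "to ", n_random %/% 2L, " nulls")
}

network_parameter_values <- function(net, target_node, parameters,
                                     null_cfg, mod_cfg, seed) {
  W <- net$weights
  need_D <- any(c("global_efficiency", "nodal_efficiency",
                  "small_worldness") %in% parameters)
  D <- if (need_D) apsp_distances_cpp(W) else NULL
  param <- character(0)
  node <- character(0)
  value <- numeric(0)
  add <- function(p, nd, v) {
    param <<- c(param, p)
    node <<- c(node, nd)
    value <<- c(value, v)
  }
  if ("global_efficiency" %in% parameters)
    add("global_efficiency", "", global_efficiency(W, D = D))
  if ("modularity" %in% parameters)
    add("modularity", "",
        optimize_modularity(W, restarts = mod_cfg$restarts,
                            seed = seed)$Q)
  if ("small_worldness" %in% parameters)
    add("small_worldness", "",
        sigma_with_retry(W, null_cfg, seed = seed, D = D))
  if ("degree_centrality" %in% parameters) {
    dc <- degree_centrality(W)
    add(rep("degree_centrality", length(dc)),
        as.character(seq_along(dc)), dc)
  }
  if ("nodal_efficiency" %in% parameters)
    add("nodal_efficiency", as.character(target_node),
        nodal_efficiency(W, target_node, D = D))
  if ("local_efficiency" %in% parameters)
    add("local_efficiency", as.character(target_node),
        local_efficiency(W, target_node))
  list(parameter = param, node = node, value = value)
}

#' Small-world realism screen
#'
#' Reports how many of the constructed networks fall below the
#' small-world boundary `sigma = 1` — a sanity check that the chosen
#' thresholds produce realistic network structure.
#'
#' @param metrics Tidy metrics table containing `small_worldness` rows.
#' @return List: `n_networks`, `n_below_one`, `fraction_below_one`.
#' @export
small_world_screen <- function(metrics) {
  sw <- metrics$value[metrics$parameter == "small_worldness"]
  if (!length(sw)) stop("no small_worldness rows in metrics table")
  list(n_networks = length(sw),
       n_below_one = sum(sw < 1),
       fraction_below_one = sum(sw < 1) / length(sw))
}
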
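#' Parcellation specification
#'
#' A parcellation is abstracted to its node count and the index of the
#' target node analysed by the nodal/local parameters.
#'
#' @param name Label, e.g. `"aal116"`.
#' @param n_nodes Number of regions (>= 3).
#' @param target_node Index of the target region (1-based).
#' @return List of class `"parcellation_spec"`.
#' @export
parcellation_spec <- function(name, n_nodes, target_node) {
  n_nodes <- as.integer(n_nodes)
  target_node <- as.integer(target_node)
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  if (target_node < 1L || target_node > n_nodes)
    stop("target_node out of range")
  structure(list(name = name, n_nodes = n_nodes,
                 target_node = target_node),
            class = "parcellation_spec")
}

#' Default pipeline configuration
#'
#' Synthetic-cohort run with a single 116-node parcellation, the
#' default 18-threshold grid, and the default null-ensemble and
#' modularity-optimizer settings.  Pass the returned list (possibly
#' modified) to [run_pipeline()], or write it as YAML/JSON and point
#' the command-line wrapper at it.
#'
#' @param seed Global seed for the whole run.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    synthetic = unclass(synthetic_config(seed = seed)),
    manifest = NULL,
    parcellations = list(
      list(name = "aal116", n_nodes = 116L, target_node = 82L)),
    grid = default_threshold_grid(),
    null_ensemble = list(n_random = 100L, n_swaps_per_edge = 10L),
    modularity = list(restarts = 10L),
    output_dir = "fcgraph-results",
    keep_networks = FALSE,
    seed = as.integer(seed)
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Missing keys fall back to [default_run_config()] values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  base <- default_run_config(seed = if (!is.null(cfg$seed)) cfg$seed else 1L)
  # replace wholesale; a recursive merge would splice user parcellations
  # into the defaults instead of replacing them
  whole <- c("parcellations", "grid", "manifest")
  merged <- utils::modifyList(base, cfg[setdiff(names(cfg), whole)])
  for (key in whole)
    if (!is.null(cfg[[key]])) merged[[key]] <- cfg[[key]]
  if (!is.null(cfg$synthetic))
    merged$synthetic <- utils::modifyList(base$synthetic, cfg$synthetic)
  if (!is.null(cfg$manifest)) merged$synthetic <- NULL
  if (is.data.frame(merged$parcellations))  # JSON simplification
    merged$parcellations <- lapply(seq_len(nrow(merged$parcellations)),
                                   function(i)
                                     as.list(merged$parcellations[i, ]))
  merged
}

stage_log <- function(fmt, ...) {
  message(sprintf("[fcgraph %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes, per parcellation: data simulation (or manifest ingestion)
#' -> Pearson connectivity -> proportional-threshold sweep -> graph
#' parameters -> AUC aggregation and hub classification ->
#' Bonferroni-corrected primary analysis -> stability analysis across
#' threshold sub-ranges -> small-world realism screen.  All result
#' tables are written as CSV under `config$output_dir`, together with a
#' JSON run summary (versions, seed, dimensions, parameter choices).
#' With `config$keep_networks = TRUE` every thresholded adjacency matrix
#' is additionally dumped as TSV under `output_dir/networks/`.
#' Deterministic given `config$seed`.
#'
#' When a `manifest` is supplied instead of a `synthetic` block, the
#' panel is read once and only the first parcellation entry is used
#' (its `n_nodes` must match the data).
#'
#' @param config Configuration list (see [default_run_config()] /
#'   [read_run_config()]), or a path to a YAML/JSON file.
#' @return Invisibly, a list with `metrics`, `aucs`, `hubs`, `primary`,
#'   `stability`, `screen` and `summary` (primary parcellation results;
#'   `metrics` etc. are per-parcellation lists).
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  has_syn <- !is.null(config$synthetic)
  has_man <- !is.null(config$manifest)
  if (has_syn == has_man)
    stop("exactly one of 'synthetic' or 'manifest' must be supplied")
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config$grid
  parcs <- lapply(config$parcellations, function(p)
    parcellation_spec(p$name, p$n_nodes, p$target_node))
  if (has_man) parcs <- parcs[1]

  panels <- list()
  metrics <- list()
  t0 <- Sys.time()
  for (i in seq_along(parcs)) {
    pc <- parcs[[i]]
    stage_log("stage simulate/ingest: parcellation '%s' (%d nodes)",
              pc$name, pc$n_nodes)
    if (has_syn) {
      syn <- config$synthetic
      syn$n_nodes <- pc$n_nodes
      syn$target_node <- pc$target_node
      syn$seed <- derive_seed(config$seed, i)
      scfg <- do.call(synthetic_config, syn)
      panels[[pc$name]] <- simulate_panel(scfg)
    } else {
      panels[[pc$name]] <- read_panel(config$manifest)
      if (panels[[pc$name]]$n_nodes != pc$n_nodes)
        stop("manifest data have ", panels[[pc$name]]$n_nodes,
             " nodes but parcellation '", pc$name, "' declares ",
             pc$n_nodes)
    }
    stage_log("stage connectivity+metrics: parcellation '%s'", pc$name)
    metrics[[pc$name]] <- compute_metric_curves(
      panels[[pc$name]], target_node = pc$target_node, grid = grid,
      null_cfg = config$null_ensemble, mod_cfg = config$modularity,
      seed = derive_seed(config$seed, 1000L + i))
    write.csv(metrics[[pc$name]],
              file.path(out_dir, paste0("metrics_", pc$name, ".csv")),
              row.names = FALSE)
    if (isTRUE(config$keep_networks))
      write_thresholded_networks(panels[[pc$name]], grid,
                                 file.path(out_dir, "networks", pc$name))
  }

  primary_name <- parcs[[1]]$name
  pm <- metrics[[primary_name]]
  stage_log("stage aggregation: AUCs and hub classification")
  aucs <- auc_table(pm, grid = grid)
  hubs <- classify_hubs(pm[pm$parameter == "degree_centrality",
                           c("subject", "session", "threshold", "node",
                             "value")])
  write.csv(aucs, file.path(out_dir, "auc.csv"), row.names = FALSE)
  write.csv(hubs$table, file.path(out_dir, "hubs.csv"), row.names = FALSE)
  write.csv(hubs$counts, file.path(out_dir, "hub_counts.csv"),
            row.names = FALSE)

  stage_log("stage inference: primary six-parameter comparison")
  primary <- run_primary_analysis(aucs, hubs, m = 6L)
  write.csv(primary, file.path(out_dir, "primary_results.csv"),
            row.names = FALSE)

  stage_log("stage stability: %d parcellation(s) x 3 threshold subsets",
            length(parcs))
  stability <- do.call(rbind, lapply(names(metrics), function(nm)
    stability_from_metrics(metrics[[nm]], grid = grid,
                           parcellation = nm)))
  rownames(stability) <- NULL
  write.csv(stability, file.path(out_dir, "stability_results.csv"),
            row.names = FALSE)

  screen <- small_world_screen(pm)
  n_networks <- vapply(metrics, function(m)
    length(unique(paste(m$subject, m$session, m$threshold))), 0)
  summary <- list(
    package_version = as.character(packageVersion("fcgraph")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    n_subjects = length(panels[[primary_name]]$subjects),
    n_sessions = length(panels[[primary_name]]$sessions),
    n_thresholds = length(grid),
    grid = grid,
    parcellations = lapply(parcs, unclass),
    networks_per_parcellation = as.list(n_networks),
    null_ensemble = config$null_ensemble,
    modularity = config$modularity,
    small_world_screen = screen,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("done in %.1f s", summary$elapsed_sec)
  invisible(list(metrics = metrics, aucs = aucs, hubs = hubs,
                 primary = primary, stability = stability,
                 screen = screen, summary = summary))
}

# Optional dump of every thresholded adjacency matrix as TSV
# (networks/<parcellation>/<subject>_<session>_p<proportion>.tsv).
write_thresholded_networks <- function(panel, grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ses in panel$sessions) {
    for (sub in panel$subjects) {
      conn <- pearson_connectivity(panel$series[[ses]][[sub]])
      nets <- threshold_sweep(conn, grid)
      for (k in seq_along(nets))
        utils::write.table(
          nets[[k]]$weights,
          file.path(dir, sprintf("%s_%s_p%.2f.tsv", sub, ses, grid[k])),
          sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  }
}

#' Pre/post threshold curves, visualized
#'
#' Mean +/- SD of a parameter's value across subjects at every
#' threshold, pre versus post — the visual counterpart of the AUCs used
#' for inference.  Requires ggplot2.
#'
#' @param metrics Tidy metrics table.
#' @param parameter Parameter name to plot.
#' @return A ggplot object.
#' @export
plot_threshold_curves <- function(metrics, parameter = "global_efficiency") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  m <- metrics[metrics$parameter == parameter, , drop = FALSE]
  if (!nrow(m)) stop("no rows for parameter ", parameter)
  agg <- aggregate(value ~ session + threshold, data = m,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  agg <- cbind(agg[c("session", "threshold")], as.data.frame(agg$value))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$threshold, y = .data$mean,
                                    colour = .data$session,
                                    fill = .data$session)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "edge retention proportion", y = parameter)
}
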
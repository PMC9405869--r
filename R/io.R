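#' Write a time-series panel to disk
#'
#' One tab-separated matrix per (subject, session) — rows are nodes,
#' columns are timepoints, no header — plus a manifest CSV with columns
#' `subject,session,path` (paths relative to the manifest's directory).
#'
#' @param panel A `"ts_panel"` (see [simulate_panel()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "ts_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ses in panel$sessions) {
    for (sub in panel$subjects) {
      fn <- sprintf("%s_%s.tsv", sub, ses)
      utils::write.table(panel$series[[ses]][[sub]],
                         file.path(dir, fn), sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(subject = sub, session = ses,
                                              path = fn)
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a time-series panel from a manifest
#'
#' The manifest is a CSV with columns `subject`, `session` and `path`
#' (relative paths are resolved against the manifest's directory).
#' Every subject must appear in both a `"pre"` and a `"post"` row; node
#' counts must agree across all matrices.
#'
#' @param manifest Path to the manifest CSV.
#' @return A `"ts_panel"`.
#' @export
read_panel <- function(manifest) {
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject", "session", "path")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$session %in% c("pre", "post")))
    stop("manifest sessions must be 'pre' or 'post'")
  subjects <- unique(tab$subject)
  for (ses in c("pre", "post")) {
    have <- tab$subject[tab$session == ses]
    missing <- setdiff(subjects, have)
    if (length(missing))
      stop("missing '", ses, "' session for subject(s): ",
           paste(missing, collapse = ", "))
  }
  root <- dirname(manifest)
  series <- list(pre = list(), post = list())
  for (k in seq_len(nrow(tab))) {
    p <- tab$path[k]
    if (!file.exists(p)) p <- file.path(root, tab$path[k])
    if (!file.exists(p))
      stop("file not found for subject ", tab$subject[k], " (",
           tab$session[k], "): ", tab$path[k])
    m <- as.matrix(read.delim(p, header = FALSE))
    dimnames(m) <- NULL
    series[[tab$session[k]]][[tab$subject[k]]] <- m
  }
  nn <- unique(vapply(unlist(series, recursive = FALSE), nrow, 1L))
  if (length(nn) != 1L)
    stop("inconsistent node counts across matrices: ",
         paste(nn, collapse = ", "))
  nt <- vapply(unlist(series, recursive = FALSE), ncol, 1L)
  if (any(nt < 3L)) stop("every matrix must have at least 3 timepoints")
  structure(list(subjects = subjects,
                 sessions = c("pre", "post"),
                 series = series[c("pre", "post")],
                 n_nodes = nn,
                 n_timepoints = unname(nt[1]),
                 config = NULL),
            class = "ts_panel")
}

#' Read precomputed connectivity matrices from a manifest
#'
#' For users who bring their own node-by-node connectivity: the manifest
#' has the same `subject,session,path` layout, each path pointing to a
#' square tab-separated Pearson correlation matrix (no header).
#'
#' @param manifest Path to the manifest CSV.
#' @return A list with `subjects`, `sessions`, and `conn` — per session,
#'   a named list of symmetric zero-diagonal matrices.
#' @export
read_connectivity_manifest <- function(manifest) {
  panel <- read_panel_raw_square(manifest)
  panel
}

read_panel_raw_square <- function(manifest) {
  tab <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject", "session", "path")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  root <- dirname(manifest)
  conn <- list(pre = list(), post = list())
  for (k in seq_len(nrow(tab))) {
    p <- tab$path[k]
    if (!file.exists(p)) p <- file.path(root, tab$path[k])
    if (!file.exists(p))
      stop("file not found for subject ", tab$subject[k], " (",
           tab$session[k], "): ", tab$path[k])
    m <- as.matrix(read.delim(p, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != ncol(m))
      stop("connectivity matrix for subject ", tab$subject[k],
           " is not square")
    diag(m) <- 0
    conn[[tab$session[k]]][[tab$subject[k]]] <- (m + t(m)) / 2
  }
  list(subjects = unique(tab$subject), sessions = c("pre", "post"),
       conn = conn)
}
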
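#' Write / read ROI time series as delimited text
#'
#' One file per subject-session, T rows x N columns, tab-separated, with a
#' header row of region labels; filename `{subject}_{session}.tsv`.
#'
#' @param ts A [roi_timeseries()].
#' @param dir Output directory (created if needed).
#' @return The written path (invisibly for the writer).
#' @export
write_timeseries_tsv <- function(ts, dir) {
  stopifnot(inherits(ts, "roi_timeseries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s.tsv", ts$subject_id, ts$session))
  utils::write.table(ts$data, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @param path File written by [write_timeseries_tsv()] (subject and session
#'   are recovered from the `{subject}_{session}.tsv` filename unless given).
#' @param subject_id,session Optional overrides.
#' @export
read_timeseries_tsv <- function(path, subject_id = NULL, session = NULL) {
  stem <- sub("\\.tsv$", "", basename(path))
  if (is.null(subject_id)) subject_id <- sub("_[^_]+$", "", stem)
  if (is.null(session)) session <- sub("^.*_", "", stem)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  roi_timeseries(m, subject_id, session)
}

#' Write / read a motion trace (T x 6 delimited text)
#'
#' Three translation columns (mm) then three rotation columns (rad).
#'
#' @param trace Motion trace (list with `subject_id`, `session`,
#'   `translations`, `rotations`).
#' @param dir Output directory.
#' @export
write_motion_tsv <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_motion.tsv", trace$subject_id,
                                 trace$session))
  utils::write.table(cbind(trace$translations, trace$rotations), path,
                     sep = "\t", row.names = FALSE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @param path File written by [write_motion_tsv()].
#' @param subject_id,session Optional overrides.
#' @export
read_motion_tsv <- function(path, subject_id = NULL, session = NULL) {
  stem <- sub("_motion\\.tsv$", "", basename(path))
  if (is.null(subject_id)) subject_id <- sub("_[^_]+$", "", stem)
  if (is.null(session)) session <- sub("^.*_", "", stem)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  list(subject_id = subject_id, session = session,
       translations = m[, 1:3, drop = FALSE],
       rotations = m[, 4:6, drop = FALSE])
}

#' Write / read the tidy behavior table
#'
#' @param behavior Data frame (subject_id, group, session, scale, score).
#' @param path CSV path.
#' @export
write_behavior_csv <- function(behavior, path) {
  utils::write.csv(behavior, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a connectivity matrix as labelled square CSV
#'
#' @param c_mat A [correlation_matrix()].
#' @param path CSV path.
#' @export
write_connectivity_csv <- function(c_mat, path) {
  utils::write.csv(as.matrix(unclass(c_mat)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  class(m) <- c("connectivity_matrix", class(m))
  m
}

#' Write a binary network as an edge list with a JSON sidecar
#'
#' One `label_i<TAB>label_j` pair per line (first index < second); the
#' sidecar `<path>.json` records the sparsity and node count.
#'
#' @param net A [threshold_by_sparsity()] result.
#' @param path Output text file.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "binary_network"))
  ed <- network_edges(net)
  writeLines(paste(ed$from, ed$to, sep = "\t"), path)
  jsonlite::write_json(
    list(sparsity = net$sparsity, n_nodes = length(net$region_labels),
         n_edges = nrow(ed)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Write / read a graph database in the gSpan exchange format
#'
#' One block per transaction: `t # <id>`, then `v <idx> <label>` lines
#' (0-based vertex indices), then `e <i> <j> <label>` lines.
#'
#' @param db List of [labeled_graph()] transactions.
#' @param path Output text file.
#' @export
write_gspan_db <- function(db, path) {
  lines <- character(0)
  for (k in seq_along(db)) {
    g <- db[[k]]
    lines <- c(lines, sprintf("t # %d", k - 1L),
               sprintf("v %d %s", seq_len(g$n) - 1L, g$labels))
    if (nrow(g$edges)) {
      lines <- c(lines, sprintf("e %d %d %s", g$edges[, 1] - 1L,
                                g$edges[, 2] - 1L, EDGE_LABEL))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gspan_db
#' @export
read_gspan_db <- function(path) {
  lines <- readLines(path)
  db <- list()
  labels <- character(0)
  edges <- NULL
  flush <- function() {
    if (length(labels)) {
      db[[length(db) + 1L]] <<- labeled_graph(
        labels, if (is.null(edges)) matrix(integer(0), 0, 2) else edges
      )
    }
  }
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(parts)) next
    if (parts[1] == "t") {
      flush()
      labels <- character(0)
      edges <- NULL
    } else if (parts[1] == "v") {
      labels[as.integer(parts[2]) + 1L] <- parts[3]
    } else if (parts[1] == "e") {
      edges <- rbind(edges, as.integer(parts[2:3]) + 1L)
    }
  }
  flush()
  db
}
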
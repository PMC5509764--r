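#' Regress nuisance confounds out of ROI time series
#'
#' Each region's series is replaced by its least-squares residual against an
#' intercept plus the supplied confound columns (e.g. the six head-motion
#' parameters, CSF and white-matter signals). With no confounds this reduces
#' to mean-centering.
#'
#' @param ts A [roi_timeseries()].
#' @param confounds Numeric matrix with `nrow(ts$data)` rows and K columns,
#'   or `NULL` for intercept-only (centering).
#' @return The residualized `roi_timeseries`.
#' @export
regress_confounds <- function(ts, confounds = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  t_len <- nrow(ts$data)
  if (is.null(confounds)) {
    design <- matrix(1, t_len, 1, dimnames = list(NULL, "intercept"))
  } else {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != t_len) {
      stop(sprintf("confounds have %d rows but the series has %d timepoints",
                   nrow(confounds), t_len))
    }
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- sprintf("confound%d", seq_len(ncol(confounds)))
    }
    design <- cbind(intercept = 1, confounds)
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1L):ncol(design)]]
    stop("confound design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  ts$data <- qr.resid(qr_d, ts$data)
  ts
}

#' Region-wise Pearson correlation matrix
#'
#' Full N x N functional connectivity matrix of a subject's ROI time series.
#'
#' @param ts A [roi_timeseries()] with at least 3 timepoints and no constant
#'   column.
#' @return Object of class `connectivity_matrix`: a symmetric numeric matrix
#'   with unit diagonal and region labels as dimnames.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (nrow(ts$data) < 3L) stop("need at least 3 timepoints for correlations")
  sds <- apply(ts$data, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series in region(s): ",
         paste(ts$region_labels[sds == 0], collapse = ", "))
  }
  m <- stats::cor(ts$data)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(ts$region_labels, ts$region_labels)
  class(m) <- c("connectivity_matrix", class(m))
  m
}

#' Sparsity threshold space
#'
#' Inclusive arithmetic sequence of sparsity levels at which every network
#' is binarized; the standard space is 5\% to 40\% in 1\% steps (36 levels).
#'
#' @param s_min,s_max Lower/upper sparsity (proportions in (0, 1]).
#' @param step Increment; `(s_max - s_min) / step` must be integral.
#' @return Numeric vector of class `sparsity_space`.
#' @export
#' @examples
#' length(build_threshold_space(0.05, 0.40, 0.01))  # 36
build_threshold_space <- function(s_min = 0.05, s_max = 0.40, step = 0.01) {
  stopifnot(s_min > 0, s_max <= 1, step > 0)
  if (s_min >= s_max) stop("s_min must be strictly less than s_max")
  n_steps <- (s_max - s_min) / step
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("threshold space span is not an integral number of steps")
  }
  values <- s_min + step * seq(0, round(n_steps))
  structure(values, class = c("sparsity_space", "numeric"),
            s_min = s_min, s_max = s_max, step = step)
}

# ranked upper-triangle pairs of a connectivity matrix: i, j (i < j), score
ranked_pairs <- function(c_mat, rank_by = c("absolute", "positive")) {
  rank_by <- match.arg(rank_by)
  n <- nrow(c_mat)
  ut <- which(upper.tri(c_mat), arr.ind = TRUE)
  score <- c_mat[ut]
  if (rank_by == "absolute") score <- abs(score)
  ord <- order(-score, ut[, 1], ut[, 2])
  list(i = ut[ord, 1], j = ut[ord, 2], n = n)
}

#' Binarize a connectivity matrix at a fixed sparsity
#'
#' Retains exactly `k = round(s * N(N-1)/2)` edges: the k pairs with the
#' largest ranking score (absolute correlation by default, signed
#' correlation with `rank_by = "positive"`). Ties are broken
#' deterministically by ascending (row, column) index so that every subject
#' ends up with an identical edge count at a given sparsity.
#'
#' @param c_mat A [correlation_matrix()] (or plain symmetric matrix with
#'   labels).
#' @param s Target sparsity in (0, 1].
#' @param rank_by `"absolute"` (default) or `"positive"`.
#' @return Object of class `binary_network`: list with `adjacency`
#'   (0/1 symmetric matrix, zero diagonal), `sparsity`, `region_labels`.
#' @export
threshold_by_sparsity <- function(c_mat, s, rank_by = c("absolute", "positive")) {
  stopifnot(is.matrix(c_mat), nrow(c_mat) == ncol(c_mat), s > 0, s <= 1)
  rp <- ranked_pairs(c_mat, rank_by)
  binary_network_from_ranked(rp, s, rownames(c_mat))
}

binary_network_from_ranked <- function(rp, s, labels) {
  n <- rp$n
  k <- round(s * n * (n - 1) / 2)
  if (k < 1) stop(sprintf("sparsity %g retains no edges for %d nodes", s, n))
  if (is.null(labels)) labels <- default_region_labels(n)
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  ii <- rp$i[seq_len(k)]
  jj <- rp$j[seq_len(k)]
  adj[cbind(ii, jj)] <- 1L
  adj[cbind(jj, ii)] <- 1L
  structure(
    list(adjacency = adj, sparsity = s, region_labels = labels),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary_network: %d nodes, %d edges (sparsity %.3f)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$sparsity))
  invisible(x)
}

#' Edge list of a binary network
#'
#' @param net A [threshold_by_sparsity()] result.
#' @return Data frame with character columns `from`, `to` (labels,
#'   `from` index < `to` index).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    from = net$region_labels[idx[, 1]],
    to = net$region_labels[idx[, 2]],
    stringsAsFactors = FALSE
  )
}
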
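as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' Nodal degree
#'
#' Number of edges incident to each node of a binary network.
#'
#' @param net A [threshold_by_sparsity()] result.
#' @return Named integer vector (one entry per region).
#' @export
nodal_degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- colSums(net$adjacency)
  stats::setNames(as.integer(d), net$region_labels)
}

#' Normalized betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node,
#' normalized by the number of pairs `(N-1)(N-2)/2` so values lie in
#' `[0, 1]`. Pairs that are disconnected contribute nothing; graphs with
#' fewer than 3 nodes return all zeros.
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- nrow(net$adjacency)
  if (n < 3L) {
    return(stats::setNames(numeric(n), net$region_labels))
  }
  b <- igraph::betweenness(as_igraph(net), directed = FALSE, weights = NA)
  stats::setNames(b / ((n - 1) * (n - 2) / 2), net$region_labels)
}

#' Nodal efficiency
#'
#' Mean inverse shortest-path length from each node to all others;
#' unreachable pairs contribute zero. A value of 1 means the node is
#' adjacent to every other node.
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector in `[0, 1]`.
#' @export
nodal_efficiency <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  n <- nrow(net$adjacency)
  if (n < 2L) return(stats::setNames(numeric(n), net$region_labels))
  d <- igraph::distances(as_igraph(net), weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  stats::setNames(rowSums(inv) / (n - 1), net$region_labels)
}

metric_names <- function() c("degree", "betweenness", "efficiency")

#' Nodal metric curves over the sparsity threshold space
#'
#' Thresholds the connectivity matrix at every sparsity in `space` and
#' computes the three nodal metrics on each binary network, yielding for
#' every node a curve of metric values across the threshold space
#' (3 x N curves in total).
#'
#' @param c_mat A [correlation_matrix()].
#' @param space A [build_threshold_space()].
#' @param rank_by Edge ranking rule, see [threshold_by_sparsity()].
#' @return Object of class `metric_curves`: list of three N x |space|
#'   matrices (`degree`, `betweenness`, `efficiency`), with the space kept
#'   as an attribute.
#' @export
metric_curves <- function(c_mat, space, rank_by = c("absolute", "positive")) {
  stopifnot(inherits(space, "sparsity_space"))
  rank_by <- match.arg(rank_by)
  rp <- ranked_pairs(c_mat, rank_by)
  labels <- rownames(c_mat)
  if (is.null(labels)) labels <- default_region_labels(rp$n)
  n_s <- length(space)
  mk <- function() matrix(NA_real_, rp$n, n_s, dimnames = list(labels, NULL))
  out <- list(degree = mk(), betweenness = mk(), efficiency = mk())
  for (si in seq_len(n_s)) {
    net <- binary_network_from_ranked(rp, space[si], labels)
    out$degree[, si] <- nodal_degree(net)
    out$betweenness[, si] <- betweenness_centrality(net)
    out$efficiency[, si] <- nodal_efficiency(net)
  }
  structure(out, class = "metric_curves", space = as.numeric(space))
}

#' Trapezoidal area under a metric curve
#'
#' The per-node summary entering group statistics: the integral of a nodal
#' metric over the sparsity axis, by the trapezoid rule on the grid of the
#' threshold space.
#'
#' @param values Numeric vector of metric values, one per sparsity level.
#' @param space The matching [build_threshold_space()] (length >= 2).
#' @return Single numeric area (unitless).
#' @export
auc_trapezoid <- function(values, space) {
  space <- as.numeric(space)
  if (length(space) < 2L) stop("AUC needs at least 2 threshold levels")
  if (length(values) != length(space)) {
    stop("curve and threshold space lengths differ")
  }
  sum(diff(space) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' AUC summaries of all metric curves
#'
#' @param curves A [metric_curves()] result.
#' @param subject,session Identifiers attached to every row.
#' @return Tidy data frame: subject, session, metric, node, auc.
#' @export
metric_auc_table <- function(curves, subject = NA_character_,
                             session = NA_character_) {
  stopifnot(inherits(curves, "metric_curves"))
  space <- attr(curves, "space")
  rows <- lapply(metric_names(), function(m) {
    vals <- apply(curves[[m]], 1, auc_trapezoid, space = space)
    data.frame(subject = subject, session = session, metric = m,
               node = rownames(curves[[m]]), auc = unname(vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hub detection by the mean-plus-one-SD degree rule
#'
#' A region counts as a hub when its (group-averaged) degree summary is at
#' least one standard deviation above the mean over all regions. The SD is
#' the population SD (divisor N) by default since the node set is the whole
#' parcellation, and the boundary is inclusive.
#'
#' @param values Numeric vector of per-node degree summaries (e.g. the AUC
#'   of the group-mean degree curve), named by region or accompanied by
#'   `labels`.
#' @param labels Region labels (defaults to `names(values)`).
#' @param sd_divisor `"population"` (divisor N, default) or `"sample"`
#'   (divisor N - 1).
#' @return Object of class `hub_set`: list with `hubs` (labels), `cutoff`,
#'   `mean`, `sd`.
#' @export
#' @examples
#' detect_hubs(c(a = 10, b = 4, c = 4, d = 4, e = 4))$hubs  # "a"
detect_hubs <- function(values, labels = names(values),
                        sd_divisor = c("population", "sample")) {
  sd_divisor <- match.arg(sd_divisor)
  n <- length(values)
  stopifnot(n >= 2L)
  if (is.null(labels)) labels <- default_region_labels(n)
  mu <- mean(values)
  s2 <- sum((values - mu)^2) / (if (sd_divisor == "population") n else n - 1L)
  s <- sqrt(s2)
  hubs <- if (s == 0) character(0) else labels[values >= mu + s]
  structure(list(hubs = hubs, cutoff = mu + s, mean = mu, sd = s,
                 sd_divisor = sd_divisor),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("hub_set: %d hub(s) [cutoff %.3f = mean %.3f + SD %.3f]\n",
              length(x$hubs), x$cutoff, x$mean, x$sd))
  if (length(x$hubs)) cat(" ", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}
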
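# Shared graph fixtures built in code.

# binary_network from an explicit edge list (bypassing thresholding)
make_bn <- function(n, edges = NULL, labels = sprintf("N%02d", seq_len(n))) {
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  if (!is.null(edges) && length(edges)) {
    edges <- matrix(as.integer(edges), ncol = 2)
    adj[edges] <- 1L
    adj[edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  structure(list(adjacency = adj, sparsity = sum(adj) / (n * (n - 1)),
                 region_labels = labels),
            class = "binary_network")
}

# random Erdos-Renyi labeled graph with labels drawn from a small alphabet
random_labeled_graph <- function(n, p_edge = 0.5, alphabet = c("A", "B", "C")) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  labeled_graph(sample(alphabet, n, replace = TRUE),
                pairs[keep, , drop = FALSE])
}

# random connected adjacency matrix (retry until connected)
random_connected_adj <- function(n, p_edge = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p_edge
    adj[pairs[keep, , drop = FALSE]] <- 1L
    adj <- adj + t(adj)
    if (adj_connected(adj)) return(adj)
  }
}

adj_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] == 1))))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# igraph's graph atlas: all undirected graphs with up to 7 vertices
atlas_adjacency <- function(idx) {
  g <- igraph::graph_from_atlas(idx)
  as.matrix(igraph::as_adjacency_matrix(g))
}
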
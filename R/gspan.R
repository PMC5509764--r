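#' Labeled undirected graph (FSM transaction)
#'
#' The unit of the frequent-subgraph-mining arm: an undirected graph whose
#' vertices carry labels from the region vocabulary. In this application a
#' subject's thresholded network has one vertex per region (labels unique),
#' but the miner never assumes label uniqueness. All edges share one uniform
#' edge label.
#'
#' @param labels Character vector of vertex labels (length = vertex count).
#' @param edges Two-column integer matrix of vertex indices (1-based), one
#'   row per undirected edge; self-loops and duplicates are rejected.
#' @return Object of class `labeled_graph` with fields `labels`, `edges`
#'   (rows normalized to u < v), `n`.
#' @export
labeled_graph <- function(labels, edges) {
  labels <- as.character(labels)
  n <- length(labels)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), 0, 2)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
  }
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- t(apply(edges, 1, sort))
    if (ncol(edges) != 2) edges <- matrix(edges, ncol = 2)  # single-edge case
    if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
      stop("duplicate edges are not allowed")
    }
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(labels = labels, edges = edges, n = n),
            class = "labeled_graph")
}

#' Convert a binary network into an FSM transaction
#'
#' Isolated regions are dropped (mining concerns connectivity patterns);
#' vertex labels are the region names.
#'
#' @param net A [threshold_by_sparsity()] result.
#' @param keep_isolated Keep degree-zero vertices (default `FALSE`).
#' @return A [labeled_graph()].
#' @export
labeled_graph_from_network <- function(net, keep_isolated = FALSE) {
  stopifnot(inherits(net, "binary_network"))
  adj <- net$adjacency
  keep <- if (keep_isolated) seq_len(nrow(adj)) else which(colSums(adj) > 0)
  adj <- adj[keep, keep, drop = FALSE]
  idx <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  labeled_graph(net$region_labels[keep], idx)
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("labeled_graph: %d vertices, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

# incidence list: for each vertex, matrix of (neighbor, edge_id)
incidence_list <- function(g) {
  inc <- vector("list", g$n)
  if (nrow(g$edges)) {
    for (e in seq_len(nrow(g$edges))) {
      u <- g$edges[e, 1]; v <- g$edges[e, 2]
      inc[[u]] <- rbind(inc[[u]], c(v, e))
      inc[[v]] <- rbind(inc[[v]], c(u, e))
    }
  }
  inc
}

graph_is_connected <- function(g) {
  if (g$n <= 1L) return(TRUE)
  if (nrow(g$edges) == 0L) return(FALSE)
  seen <- logical(g$n)
  stack <- 1L
  seen[1L] <- TRUE
  inc <- incidence_list(g)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    nb <- inc[[v]]
    if (!is.null(nb)) {
      new <- nb[!seen[nb[, 1]], 1]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
  }
  all(seen)
}

EDGE_LABEL <- "-"

# Bytewise (C-locale) vectorized string comparison a < b; label order must
# not depend on the session's collation locale.
str_less_c <- function(a, b) {
  mapply(function(x, y) {
    if (x == y) return(FALSE)
    xs <- utf8ToInt(x); ys <- utf8ToInt(y)
    k <- min(length(xs), length(ys))
    for (t in seq_len(k)) if (xs[t] != ys[t]) return(xs[t] < ys[t])
    length(xs) < length(ys)
  }, a, b, USE.NAMES = FALSE)
}

dfs_code_key <- function(tuples) {
  paste(sprintf("(%d,%d,%s,%s,%s)", tuples$i, tuples$j,
                tuples$li, tuples$le, tuples$lj), collapse = "")
}

new_dfs_code <- function(i, j, li, lj) {
  structure(
    list(tuples = data.frame(i = i, j = j, li = li, le = EDGE_LABEL, lj = lj,
                             stringsAsFactors = FALSE),
         key = NA_character_),
    class = "dfs_code"
  )
}

finalize_code <- function(code) {
  code$key <- dfs_code_key(code$tuples)
  code
}

#' @export
print.dfs_code <- function(x, ...) {
  cat("dfs_code:", x$key, "\n")
  invisible(x)
}

#' Graph encoded by a DFS code
#'
#' @param code A `dfs_code` (e.g. from [min_dfs_code()]).
#' @return The [labeled_graph()] the code spells out.
#' @export
graph_from_dfs_code <- function(code) {
  tp <- code$tuples
  n <- max(tp$i, tp$j) + 1L
  labels <- character(n)
  labels[tp$i + 1L] <- tp$li
  labels[tp$j + 1L] <- tp$lj
  labeled_graph(labels, cbind(tp$i + 1L, tp$j + 1L))
}

# --- DFS-code search machinery -------------------------------------------
#
# A DFS code is the edge-tuple sequence of a depth-first traversal; gSpan
# compares codes by its edge order (backward before forward, deeper forward
# first, then labels) and uses the lexicographic minimum over all
# traversals as a graph's canonical label. Both min_dfs_code() and the
# miner enumerate "rightmost extensions" of partial traversals:
#   - backward edges from the rightmost vertex to a rightmost-path vertex,
#     emitted in increasing target order;
#   - forward edges from any rightmost-path vertex to an undiscovered
#     vertex.
# A traversal state tracks the discovery map (pattern index -> graph
# vertex), the DFS-tree parent of each pattern index, which graph edges are
# used, and the largest backward target already emitted from the current
# rightmost vertex.

new_state <- function(gid, a, b, eid, n_edges) {
  used <- logical(n_edges)
  used[eid] <- TRUE
  list(gid = gid, vmap = c(a, b), parent = c(NA_integer_, 0L),
       used = used, lastback = -1L)
}

rightmost_path <- function(state) {
  # pattern indices (0-based) from root to rightmost vertex
  r <- length(state$vmap) - 1L
  path <- r
  while (!is.na(state$parent[path[1L] + 1L])) {
    path <- c(state$parent[path[1L] + 1L], path)
  }
  path
}

# All rightmost extensions of a traversal state within its host graph.
# Returns a list of candidates: list(kind, i, j, li, lj, eid, pi/target).
state_extensions <- function(state, labels, inc) {
  out <- list()
  r <- length(state$vmap) - 1L
  rmpath <- rightmost_path(state)
  gv_rm <- state$vmap[r + 1L]
  pos <- match(seq_along(state$vmap) - 1L, rmpath)  # pattern idx -> on-path?

  nb <- inc[[gv_rm]]
  if (!is.null(nb)) {
    for (row in seq_len(nrow(nb))) {
      w <- nb[row, 1]; eid <- nb[row, 2]
      if (state$used[eid]) next
      pj_all <- which(state$vmap == w) - 1L
      for (pj in pj_all) {
        if (!(pj %in% rmpath) || pj >= r) next
        if (pj <= state$lastback) next
        out[[length(out) + 1L]] <- list(
          kind = "b", i = r, j = pj,
          li = labels[gv_rm], lj = labels[w], eid = eid, target = pj
        )
      }
    }
  }
  for (pi in rmpath) {
    x <- state$vmap[pi + 1L]
    nb <- inc[[x]]
    if (is.null(nb)) next
    for (row in seq_len(nrow(nb))) {
      y <- nb[row, 1]; eid <- nb[row, 2]
      if (state$used[eid]) next
      if (y %in% state$vmap) next
      out[[length(out) + 1L]] <- list(
        kind = "f", i = pi, j = r + 1L,
        li = labels[x], lj = labels[y], eid = eid, target = y, from = pi
      )
    }
  }
  out
}

apply_extension <- function(state, ext) {
  state$used[ext$eid] <- TRUE
  if (ext$kind == "b") {
    state$lastback <- ext$j
  } else {
    state$vmap <- c(state$vmap, ext$target)
    state$parent <- c(state$parent, ext$i)
    state$lastback <- -1L
  }
  state
}

ext_tuple_id <- function(ext) {
  paste(ext$kind, ext$i, ext$j, ext$li, ext$lj, sep = "\r")
}

# gSpan within-step extension order: all candidates at one growth step share
# the same rightmost context, so backward edges (ascending target) precede
# forward edges (descending origin), with vertex-label order breaking ties.
order_tuple_ids <- function(ids) {
  parts <- strsplit(ids, "\r", fixed = TRUE)
  kind <- vapply(parts, `[[`, "", 1L)
  i <- as.integer(vapply(parts, `[[`, "", 2L))
  j <- as.integer(vapply(parts, `[[`, "", 3L))
  li <- vapply(parts, `[[`, "", 4L)
  lj <- vapply(parts, `[[`, "", 5L)
  structural <- ifelse(kind == "b", j, -i)
  ids[order(kind, structural, li, lj, method = "radix")]
}

#' Minimum DFS code (gSpan canonical label)
#'
#' Computes the lexicographically smallest DFS code over all depth-first
#' traversals of a connected labeled graph, using the gSpan edge order
#' (backward edges precede forward edges, deeper forward origins first,
#' then vertex labels). Two graphs are isomorphic exactly when their
#' minimum DFS codes are equal.
#'
#' @param g A connected [labeled_graph()] with at least one edge.
#' @return Object of class `dfs_code`: list with `tuples` (data frame of
#'   columns i, j, li, le, lj) and the string `key`.
#' @export
#' @examples
#' g <- labeled_graph(c("A", "B"), rbind(c(1, 2)))
#' min_dfs_code(g)$key
min_dfs_code <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  if (nrow(g$edges) == 0L) stop("minimum DFS code needs at least one edge")
  if (!graph_is_connected(g)) stop("graph must be connected")
  inc <- incidence_list(g)
  m <- nrow(g$edges)

  # initial states grouped by the (li, lj) label pair, smallest pair first
  init <- list()
  for (e in seq_len(m)) {
    u <- g$edges[e, 1]; v <- g$edges[e, 2]
    for (ori in list(c(u, v), c(v, u))) {
      key <- paste(g$labels[ori[1]], g$labels[ori[2]], sep = "\r")
      init[[key]] <- c(init[[key]], list(new_state(1L, ori[1], ori[2], e, m)))
    }
  }
  lab_pairs <- do.call(rbind, strsplit(names(init), "\r", fixed = TRUE))
  ord <- order(lab_pairs[, 1], lab_pairs[, 2], method = "radix")

  for (k in ord) {
    res <- min_code_search(init[[names(init)[k]]], g$labels, inc,
                           list(i = integer(0), j = integer(0),
                                li = character(0), lj = character(0)),
                           m)
    if (!is.null(res)) {
      code <- new_dfs_code(
        c(0L, res$i), c(1L, res$j),
        c(lab_pairs[k, 1], res$li), c(lab_pairs[k, 2], res$lj)
      )
      return(finalize_code(code))
    }
  }
  stop("internal error: no complete DFS traversal found")  # nocov
}

# Ordered depth-first search over traversal prefixes; the first complete
# code reached is the minimum (prefixes are explored in gSpan order, and
# all complete codes have the same length, so no shorter/longer ambiguity).
min_code_search <- function(states, labels, inc, acc, m) {
  if (length(acc$i) + 1L == m) return(acc)
  groups <- list()
  for (st in states) {
    for (ext in state_extensions(st, labels, inc)) {
      id <- ext_tuple_id(ext)
      groups[[id]] <- c(groups[[id]], list(list(st = st, ext = ext)))
    }
  }
  if (length(groups) == 0L) return(NULL)  # dead end (uncoverable edge)
  for (id in order_tuple_ids(names(groups))) {
    members <- groups[[id]]
    ext0 <- members[[1L]]$ext
    nxt <- lapply(members, function(me) apply_extension(me$st, me$ext))
    res <- min_code_search(
      nxt, labels, inc,
      list(i = c(acc$i, ext0$i), j = c(acc$j, ext0$j),
           li = c(acc$li, ext0$li), lj = c(acc$lj, ext0$lj)),
      m
    )
    if (!is.null(res)) return(res)
  }
  NULL
}

# --- support counting ------------------------------------------------------

#' Transaction support of a pattern
#'
#' Number of transactions in a graph database containing at least one
#' label-preserving, vertex-injective embedding of the pattern (multiple
#' embeddings within one transaction count once).
#'
#' @param pattern A connected [labeled_graph()].
#' @param db List of [labeled_graph()] transactions (a graph database).
#' @return Integer support count.
#' @export
subgraph_support <- function(pattern, db) {
  stopifnot(inherits(pattern, "labeled_graph"))
  if (!graph_is_connected(pattern)) stop("pattern must be connected")
  sum(vapply(db, function(g) has_embedding(pattern, g), logical(1)))
}

# Backtracking subgraph-isomorphism test (pattern vertices assigned in a
# connected order; candidates filtered by label and adjacency).
has_embedding <- function(pattern, g) {
  np <- pattern$n
  if (np > g$n || nrow(pattern$edges) > nrow(g$edges)) return(FALSE)
  adj_g <- matrix(FALSE, g$n, g$n)
  if (nrow(g$edges)) {
    adj_g[g$edges] <- TRUE
    adj_g[g$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  # connected assignment order + earlier neighbors to check
  order_v <- integer(0)
  placed <- logical(np)
  pinc <- incidence_list(pattern)
  frontier <- 1L
  while (length(order_v) < np) {
    if (length(frontier) == 0L) {
      frontier <- which(!placed)[1L]  # (pattern is connected; defensive)
    }
    v <- frontier[1L]; frontier <- frontier[-1L]
    if (placed[v]) next
    placed[v] <- TRUE
    order_v <- c(order_v, v)
    if (!is.null(pinc[[v]])) frontier <- c(frontier, pinc[[v]][, 1])
  }
  preds <- lapply(seq_len(np), function(k) {
    v <- order_v[k]
    nb <- if (is.null(pinc[[v]])) integer(0) else pinc[[v]][, 1]
    match(intersect(nb, order_v[seq_len(k - 1L)]), order_v)
  })
  assign_vec <- integer(np)
  recurse <- function(k) {
    if (k > np) return(TRUE)
    v <- order_v[k]
    cand <- which(g$labels == pattern$labels[v])
    cand <- setdiff(cand, assign_vec[seq_len(k - 1L)])
    for (p in preds[[k]]) cand <- cand[adj_g[assign_vec[p], cand]]
    for (cv in cand) {
      assign_vec[k] <<- cv
      if (recurse(k + 1L)) return(TRUE)
    }
    FALSE
  }
  recurse(1L)
}

# --- gSpan mining ----------------------------------------------------------

#' Mine frequent connected subgraphs (gSpan)
#'
#' Enumerates, up to isomorphism, every connected subgraph pattern whose
#' transaction support meets `min_support` and whose edge count lies within
#' `[min_edges, max_edges]`. Patterns are grown by rightmost-path extension
#' of DFS codes; every candidate whose code is not the minimum DFS code of
#' its graph is pruned (it is generated elsewhere from its canonical code),
#' and anti-monotonicity guarantees the support filter never loses a
#' frequent pattern.
#'
#' @param db List of [labeled_graph()] transactions.
#' @param min_support Minimum number of supporting transactions (>= 1).
#' @param min_edges,max_edges Pattern size bounds (edge counts); patterns
#'   of 2-6 edges by default.
#' @return Object of class `fsm_result`: list of frequent patterns, each a
#'   list with `key` (minimum DFS code string), `tuples`, `support`,
#'   `edge_count`, `graph`. Mining parameters are kept as attributes.
#' @export
gspan_mine <- function(db, min_support, min_edges = 2L, max_edges = 6L) {
  if (length(db) == 0L) stop("graph database is empty")
  min_support <- as.integer(min_support)
  min_edges <- as.integer(min_edges)
  max_edges <- as.integer(max_edges)
  stopifnot(min_support >= 1L, min_edges >= 1L, min_edges <= max_edges)
  db <- lapply(db, function(g) {
    stopifnot(inherits(g, "labeled_graph"))
    g
  })
  incs <- lapply(db, incidence_list)
  n_edges_g <- vapply(db, function(g) nrow(g$edges), integer(1))

  results <- new.env(parent = emptyenv())
  results$patterns <- list()

  # frequent single edges, by sorted label pair
  pair_rows <- list()
  for (gid in seq_along(db)) {
    g <- db[[gid]]
    if (nrow(g$edges) == 0L) next
    la <- g$labels[g$edges[, 1]]
    lb <- g$labels[g$edges[, 2]]
    swap <- str_less_c(lb, la)
    lo <- ifelse(swap, lb, la); hi <- ifelse(swap, la, lb)
    pair_rows[[gid]] <- unique(data.frame(lo = lo, hi = hi,
                                          stringsAsFactors = FALSE))
  }
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(empty_fsm_result(length(db), min_support, min_edges, max_edges))
  }
  tab <- stats::aggregate(list(support = seq_len(nrow(pairs))),
                          by = list(lo = pairs$lo, hi = pairs$hi),
                          FUN = length)
  tab <- tab[tab$support >= min_support, , drop = FALSE]
  tab <- tab[order(tab$lo, tab$hi, method = "radix"), , drop = FALSE]

  for (row in seq_len(nrow(tab))) {
    la <- tab$lo[row]; lb <- tab$hi[row]
    states <- list()
    for (gid in seq_along(db)) {
      g <- db[[gid]]
      if (nrow(g$edges) == 0L) next
      for (e in seq_len(nrow(g$edges))) {
        u <- g$edges[e, 1]; v <- g$edges[e, 2]
        oris <- list()
        if (g$labels[u] == la && g$labels[v] == lb) oris <- c(oris, list(c(u, v)))
        if (g$labels[v] == la && g$labels[u] == lb) oris <- c(oris, list(c(v, u)))
        for (ori in oris) {
          states <- c(states, list(new_state(gid, ori[1], ori[2], e,
                                             n_edges_g[gid])))
        }
      }
    }
    if (!length(states)) next
    code <- finalize_code(new_dfs_code(0L, 1L, la, lb))
    gspan_grow(code, states, db, incs, min_support, min_edges, max_edges,
               results)
  }

  pats <- results$patterns
  if (length(pats)) {
    ord <- order(vapply(pats, `[[`, integer(1), "edge_count"),
                 vapply(pats, `[[`, character(1), "key"), method = "radix")
    pats <- pats[ord]
  }
  structure(pats, class = "fsm_result",
            n_transactions = length(db), min_support = min_support,
            min_edges = min_edges, max_edges = max_edges)
}

empty_fsm_result <- function(n, min_support, min_edges, max_edges) {
  structure(list(), class = "fsm_result", n_transactions = n,
            min_support = min_support, min_edges = min_edges,
            max_edges = max_edges)
}

#' @export
print.fsm_result <- function(x, ...) {
  cat(sprintf(
    "fsm_result: %d frequent pattern(s) [support >= %d of %d, %d-%d edges]\n",
    length(x), attr(x, "min_support"), attr(x, "n_transactions"),
    attr(x, "min_edges"), attr(x, "max_edges")
  ))
  invisible(x)
}

gspan_grow <- function(code, states, db, incs, min_support, min_edges,
                       max_edges, results) {
  pattern <- graph_from_dfs_code(code)
  if (min_dfs_code(pattern)$key != code$key) return(invisible(NULL))
  ec <- nrow(code$tuples)
  support <- length(unique(vapply(states, `[[`, integer(1), "gid")))
  if (ec >= min_edges) {
    results$patterns[[length(results$patterns) + 1L]] <- list(
      key = code$key, tuples = code$tuples, support = support,
      edge_count = ec, graph = pattern
    )
  }
  if (ec >= max_edges) return(invisible(NULL))

  groups <- list()
  for (st in states) {
    labels_g <- db[[st$gid]]$labels
    for (ext in state_extensions(st, labels_g, incs[[st$gid]])) {
      id <- ext_tuple_id(ext)
      groups[[id]] <- c(groups[[id]], list(list(st = st, ext = ext)))
    }
  }
  if (!length(groups)) return(invisible(NULL))
  for (id in order_tuple_ids(names(groups))) {
    members <- groups[[id]]
    gids <- unique(vapply(members, function(me) me$st$gid, integer(1)))
    if (length(gids) < min_support) next
    ext0 <- members[[1L]]$ext
    new_code <- code
    new_code$tuples <- rbind(
      new_code$tuples,
      data.frame(i = ext0$i, j = ext0$j, li = ext0$li, le = EDGE_LABEL,
                 lj = ext0$lj, stringsAsFactors = FALSE)
    )
    new_code <- finalize_code(new_code)
    nxt <- lapply(members, function(me) apply_extension(me$st, me$ext))
    gspan_grow(new_code, nxt, db, incs, min_support, min_edges, max_edges,
               results)
  }
  invisible(NULL)
}

#' Compare frequent-pattern sets between sessions
#'
#' Set algebra on minimum-DFS-code keys of two mining results obtained with
#' identical parameters: patterns that appeared (post only), disappeared
#' (pre only), and persisted (both).
#'
#' @param pre,post [gspan_mine()] results for the two sessions.
#' @return List with character-key vectors `appeared`, `disappeared`,
#'   `persistent`, and the corresponding pattern objects
#'   (`appeared_patterns`, `disappeared_patterns`).
#' @export
compare_frequent_patterns <- function(pre, post) {
  stopifnot(inherits(pre, "fsm_result"), inherits(post, "fsm_result"))
  for (a in c("min_support", "min_edges", "max_edges")) {
    if (!identical(attr(pre, a), attr(post, a))) {
      stop("mining parameters differ between sessions: ", a)
    }
  }
  kpre <- vapply(pre, `[[`, character(1), "key")
  kpost <- vapply(post, `[[`, character(1), "key")
  appeared <- setdiff(kpost, kpre)
  disappeared <- setdiff(kpre, kpost)
  list(
    appeared = appeared,
    disappeared = disappeared,
    persistent = intersect(kpre, kpost),
    appeared_patterns = post[kpost %in% appeared],
    disappeared_patterns = pre[kpre %in% disappeared]
  )
}
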
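# Independent brute-force oracles. Everything here recomputes quantities by
# direct enumeration (simple paths, vertex permutations, injective maps,
# exhaustive sign patterns) so that package results can be checked against
# an implementation that shares no code with the package internals.

## ---- shortest-path metrics by exhaustive simple-path enumeration ----------

# Distances by Floyd-Warshall, then explicit enumeration of every shortest
# path (depth-first, following strictly distance-decreasing steps);
# betweenness and efficiency are computed from the enumerated paths.
oracle_path_metrics <- function(adj) {
  n <- nrow(adj)
  dmat <- matrix(Inf, n, n)
  diag(dmat) <- 0
  dmat[adj == 1] <- 1
  for (k in seq_len(n)) {
    via <- outer(dmat[, k], dmat[k, ], "+")
    dmat <- pmin(dmat, via)
  }
  btw <- numeric(n)
  if (n >= 3) {
    for (s in 1:(n - 1)) {
      for (t in (s + 1):n) {
        if (!is.finite(dmat[s, t])) next
        paths <- list()
        rec <- function(v, path) {
          if (v == t) {
            paths[[length(paths) + 1L]] <<- path
            return(invisible())
          }
          for (w in which(adj[v, ] == 1)) {
            if (is.finite(dmat[w, t]) && dmat[w, t] == dmat[v, t] - 1) {
              rec(w, c(path, w))
            }
          }
        }
        rec(s, s)
        sigma <- length(paths)
        interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
        if (length(interior)) {
          btw <- btw + tabulate(interior, nbins = n) / sigma
        }
      }
    }
  }
  inv <- 1 / dmat
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  list(
    betweenness = if (n >= 3) btw / ((n - 1) * (n - 2) / 2) else numeric(n),
    efficiency = if (n >= 2) rowSums(inv) / (n - 1) else numeric(n),
    dist = dmat
  )
}

## ---- minimum DFS code by exhaustive traversal enumeration ------------------

# bytewise string comparison (C order), independent of the package helper
oracle_str_cmp <- function(a, b) {
  if (a == b) return(0L)
  xs <- utf8ToInt(a); ys <- utf8ToInt(b)
  k <- min(length(xs), length(ys))
  for (t in seq_len(k)) {
    if (xs[t] != ys[t]) return(if (xs[t] < ys[t]) -1L else 1L)
  }
  if (length(xs) < length(ys)) -1L else 1L
}

# gSpan edge order on complete tuples (i, j, li, lj); returns -1/0/1
oracle_tuple_cmp <- function(e1, e2) {
  f1 <- e1$j > e1$i
  f2 <- e2$j > e2$i
  if (f1 && f2) {
    if (e1$j != e2$j) return(if (e1$j < e2$j) -1L else 1L)
    if (e1$i != e2$i) return(if (e1$i > e2$i) -1L else 1L)
  } else if (!f1 && !f2) {
    if (e1$i != e2$i) return(if (e1$i < e2$i) -1L else 1L)
    if (e1$j != e2$j) return(if (e1$j < e2$j) -1L else 1L)
  } else if (!f1 && f2) {
    return(if (e1$i < e2$j) -1L else 1L)
  } else {
    return(if (e1$j <= e2$i) -1L else 1L)
  }
  c1 <- oracle_str_cmp(e1$li, e2$li)
  if (c1 != 0L) return(c1)
  oracle_str_cmp(e1$lj, e2$lj)
}

oracle_code_cmp <- function(a, b) {
  for (k in seq_len(min(length(a), length(b)))) {
    cmp <- oracle_tuple_cmp(a[[k]], b[[k]])
    if (cmp != 0L) return(cmp)
  }
  0L  # complete codes of the same graph have equal length
}

# Enumerate every DFS traversal's code of a connected labeled graph
# (rightmost extension grammar, no pruning) and return them all.
oracle_all_dfs_codes <- function(g) {
  n <- g$n
  adj <- matrix(FALSE, n, n)
  eid <- matrix(0L, n, n)
  m <- nrow(g$edges)
  for (e in seq_len(m)) {
    u <- g$edges[e, 1]; v <- g$edges[e, 2]
    adj[u, v] <- adj[v, u] <- TRUE
    eid[u, v] <- eid[v, u] <- e
  }
  codes <- list()
  rec <- function(map, parent, used, lastb, code) {
    if (length(code) == m) {
      codes[[length(codes) + 1L]] <<- code
      return(invisible())
    }
    r <- length(map)                    # rightmost pattern vertex (1-based)
    path <- r
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    gv <- map[r]
    # backward extensions from the rightmost vertex
    for (pj in path) {
      if (pj >= r || pj <= lastb) next
      w <- map[pj]
      if (adj[gv, w] && !used[eid[gv, w]]) {
        tup <- list(i = r - 1L, j = pj - 1L, li = g$labels[gv],
                    lj = g$labels[w])
        rec(map, parent, `[<-`(used, eid[gv, w], TRUE), pj,
            c(code, list(tup)))
      }
    }
    # forward extensions from any rightmost-path vertex
    for (pi in path) {
      x <- map[pi]
      for (y in which(adj[x, ])) {
        if (y %in% map || used[eid[x, y]]) next
        tup <- list(i = pi - 1L, j = r, li = g$labels[x], lj = g$labels[y])
        rec(c(map, y), c(parent, pi), `[<-`(used, eid[x, y], TRUE), 0L,
            c(code, list(tup)))
      }
    }
  }
  for (e in seq_len(m)) {
    for (ori in list(g$edges[e, ], rev(g$edges[e, ]))) {
      tup <- list(i = 0L, j = 1L, li = g$labels[ori[1]], lj = g$labels[ori[2]])
      rec(c(ori[1], ori[2]), c(NA_integer_, 1L),
          `[<-`(logical(m), e, TRUE), 0L, list(tup))
    }
  }
  codes
}

oracle_min_dfs_key <- function(g) {
  codes <- oracle_all_dfs_codes(g)
  best <- codes[[1]]
  for (code in codes[-1]) {
    if (oracle_code_cmp(code, best) < 0L) best <- code
  }
  paste(vapply(best, function(tp) {
    sprintf("(%d,%d,%s,-,%s)", tp$i, tp$j, tp$li, tp$lj)
  }, character(1)), collapse = "")
}

## ---- subgraph isomorphism / mining oracles ---------------------------------

# all injective label-preserving maps, checked by direct recursion
oracle_has_embedding <- function(plabels, pedges, g) {
  np <- length(plabels)
  assign_vec <- integer(np)
  adj <- matrix(FALSE, g$n, g$n)
  if (nrow(g$edges)) {
    adj[g$edges] <- TRUE
    adj[g$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  rec <- function(k) {
    if (k > np) return(TRUE)
    for (cand in which(g$labels == plabels[k])) {
      if (cand %in% assign_vec[seq_len(k - 1L)]) next
      ok <- TRUE
      if (nrow(pedges)) {
        for (e in seq_len(nrow(pedges))) {
          a <- pedges[e, 1]; b <- pedges[e, 2]
          if (a <= k && b <= k && max(a, b) == k) {
            other <- assign_vec[min(a, b)]
            if (min(a, b) < k && !adj[other, cand]) { ok <- FALSE; break }
          }
        }
      }
      if (!ok) next
      assign_vec[k] <<- cand
      if (rec(k + 1L)) return(TRUE)
      assign_vec[k] <<- 0L
    }
    FALSE
  }
  rec(1L)
}

perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1L)
  out <- NULL
  for (pos in seq_len(k)) {
    block <- cbind(sub, k)
    if (pos < k) {
      tmp <- block[, pos]
      block[, pos] <- k
      block[, k] <- tmp
    }
    out <- rbind(out, block)
  }
  out
}

# canonical string of a small labeled graph: vertices are first sorted by
# label, then the edge list is minimized over every label-preserving
# relabeling (permutations within equal-label blocks) — an exhaustive
# canonical form that never mixes labels
oracle_canonical_key <- function(labels, edges) {
  o <- order(labels)
  labs <- labels[o]
  inv0 <- integer(length(o)); inv0[o] <- seq_along(o)
  e0 <- if (nrow(edges)) {
    cbind(inv0[edges[, 1]], inv0[edges[, 2]])
  } else {
    edges
  }
  blocks <- split(seq_along(labs), labs)
  perm_sets <- lapply(blocks, function(ix) {
    ps <- perms_of(length(ix))
    lapply(seq_len(nrow(ps)), function(r) ix[ps[r, ]])
  })
  combos <- expand.grid(lapply(perm_sets, seq_along))
  best <- NULL
  for (ci in seq_len(nrow(combos))) {
    new_id <- integer(length(labs))
    for (bi in seq_along(perm_sets)) {
      new_id[blocks[[bi]]] <- perm_sets[[bi]][[combos[ci, bi]]]
    }
    ekey <- ""
    if (nrow(e0)) {
      e2 <- cbind(new_id[e0[, 1]], new_id[e0[, 2]])
      e2 <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
      e2 <- e2[order(e2[, 1], e2[, 2]), , drop = FALSE]
      ekey <- paste(e2[, 1], e2[, 2], sep = "-", collapse = ";")
    }
    key <- paste(paste(labs, collapse = ","), ekey, sep = "|")
    if (is.null(best) || key < best) best <- key
  }
  best
}

# brute-force frequent-subgraph miner: enumerate connected edge subsets of
# every transaction, deduplicate by permutation-canonical key, count
# transaction support by brute-force embedding search
oracle_mine <- function(db, min_support, min_edges, max_edges) {
  patterns <- list()
  for (g in db) {
    m <- nrow(g$edges)
    if (m < min_edges) next
    for (k in min_edges:min(max_edges, m)) {
      for (comb in utils::combn(m, k, simplify = FALSE)) {
        sub_edges <- g$edges[comb, , drop = FALSE]
        verts <- sort(unique(as.vector(sub_edges)))
        rel <- matrix(match(as.vector(sub_edges), verts), ncol = 2)
        labs <- g$labels[verts]
        # connectivity of the edge-induced subgraph
        sub_adj <- matrix(0L, length(verts), length(verts))
        sub_adj[rel] <- 1L
        sub_adj[rel[, c(2, 1), drop = FALSE]] <- 1L
        if (!adj_connected(sub_adj)) next
        key <- oracle_canonical_key(labs, rel)
        if (is.null(patterns[[key]])) {
          patterns[[key]] <- list(labels = labs, edges = rel)
        }
      }
    }
  }
  out <- list()
  for (key in names(patterns)) {
    pat <- patterns[[key]]
    sup <- sum(vapply(db, function(g) {
      oracle_has_embedding(pat$labels, pat$edges, g)
    }, logical(1)))
    if (sup >= min_support) out[[key]] <- sup
  }
  out
}

## ---- exact sign-flip permutation p-value -----------------------------------

oracle_exact_signflip_p <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_stats <- as.numeric(signs %*% d) / n
  obs <- mean(d)
  mean(abs(null_stats) >= abs(obs) - 1e-12)
}
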
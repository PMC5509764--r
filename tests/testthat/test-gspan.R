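triangle <- function(labels = c("A", "B", "C")) {
  labeled_graph(labels, rbind(c(1, 2), c(2, 3), c(1, 3)))
}

test_that("minimum DFS code handles elementary cases", {
  g <- labeled_graph(c("A", "B"), rbind(c(1, 2)))
  expect_equal(min_dfs_code(g)$key, "(0,1,A,-,B)")
  # order of vertex ids is irrelevant
  g2 <- labeled_graph(c("B", "A"), rbind(c(1, 2)))
  expect_equal(min_dfs_code(g2)$key, "(0,1,A,-,B)")
  expect_error(min_dfs_code(labeled_graph(c("A", "B", "C"), rbind(c(1, 2)))),
               "connected")
  expect_error(min_dfs_code(labeled_graph("A", NULL)), "one edge")
})

test_that("isomorphic graphs share one minimum DFS code", {
  base_key <- min_dfs_code(triangle())$key
  for (perm in list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2), c(3, 2, 1))) {
    labs <- c("A", "B", "C")[perm]
    inv <- order(perm)
    g <- labeled_graph(labs, rbind(inv[c(1, 2)], inv[c(2, 3)], inv[c(1, 3)]))
    expect_equal(min_dfs_code(g)$key, base_key)
  }
})

test_that("minimum DFS code equals the exhaustive-traversal minimum", {
  # every connected 4-vertex graph under every {A,B} labeling
  pairs4 <- t(utils::combn(4, 2))
  for (mask in 1:63) {
    sel <- as.logical(bitwAnd(mask, 2^(0:5)))
    edges <- pairs4[sel, , drop = FALSE]
    adj <- matrix(0L, 4, 4)
    adj[edges] <- 1L; adj[edges[, c(2, 1), drop = FALSE]] <- 1L
    if (!adj_connected(adj)) next
    for (lab_mask in 0:15) {
      labels <- ifelse(as.logical(bitwAnd(lab_mask, 2^(0:3))), "B", "A")
      g <- labeled_graph(labels, edges)
      expect_equal(min_dfs_code(g)$key, oracle_min_dfs_key(g),
                   label = sprintf("edges mask %d labels %s", mask,
                                   paste(labels, collapse = "")))
    }
  }
})

test_that("transaction support counts embeddings correctly", {
  db <- list(triangle(), triangle(), triangle())
  edge_ab <- labeled_graph(c("A", "B"), rbind(c(1, 2)))
  expect_equal(subgraph_support(edge_ab, db), 3)
  absent <- labeled_graph(c("A", "Z"), rbind(c(1, 2)))
  expect_equal(subgraph_support(absent, db), 0)
  # multiple embeddings in one transaction count once
  two_ab <- labeled_graph(c("A", "B", "A", "B"),
                          rbind(c(1, 2), c(3, 4), c(2, 3)))
  expect_equal(subgraph_support(edge_ab, list(two_ab)), 1)
  # random patterns agree with the brute-force embedding oracle
  set.seed(21)
  for (rep in 1:30) {
    g_db <- lapply(1:10, function(i) random_labeled_graph(6, 0.5))
    pat <- random_labeled_graph(4, 0.6)
    if (nrow(pat$edges) < 1 || !fcmine:::graph_is_connected(pat)) next
    expect_equal(
      subgraph_support(pat, g_db),
      sum(vapply(g_db, function(g) {
        oracle_has_embedding(pat$labels, pat$edges, g)
      }, logical(1)))
    )
  }
})

test_that("mining three identical triangles gives the hand enumeration", {
  db <- list(triangle(), triangle(), triangle())
  res <- gspan_mine(db, min_support = 3, min_edges = 2, max_edges = 6)
  expect_length(res, 4)  # 3 two-edge paths + the triangle
  expect_equal(sort(vapply(res, `[[`, integer(1), "edge_count")),
               c(2L, 2L, 2L, 3L))
  expect_true(all(vapply(res, `[[`, integer(1), "support") == 3L))
  # with single edges allowed: + AB, AC, BC
  res1 <- gspan_mine(db, min_support = 3, min_edges = 1, max_edges = 6)
  expect_length(res1, 7)
  # support threshold above the database size yields nothing
  expect_length(gspan_mine(db, min_support = 4), 0)
  expect_error(gspan_mine(list(), 1), "empty")
})

test_that("mining equals the brute-force enumeration oracle", {
  set.seed(33)
  for (rep in 1:10) {
    db <- lapply(1:8, function(i) random_labeled_graph(6, 0.45))
    res <- gspan_mine(db, min_support = 3, min_edges = 1, max_edges = 4)
    got <- stats::setNames(
      vapply(res, `[[`, integer(1), "support"),
      vapply(res, function(p) {
        oracle_canonical_key(p$graph$labels, p$graph$edges)
      }, character(1))
    )
    want <- unlist(oracle_mine(db, 3, 1, 4))
    if (is.null(want)) want <- integer(0)
    expect_setequal(names(got), names(want))
    expect_equal(got[order(names(got))],
                 want[order(names(want))], ignore_attr = FALSE)
  }
})

test_that("mining output is invariant to transaction order and vertex ids", {
  set.seed(44)
  db <- lapply(1:6, function(i) random_labeled_graph(6, 0.5))
  res_a <- gspan_mine(db, min_support = 3, min_edges = 1, max_edges = 4)
  db_shuffled <- db[sample(length(db))]
  db_renumbered <- lapply(db_shuffled, function(g) {
    perm <- sample(g$n)
    inv <- order(perm)
    labeled_graph(g$labels[perm],
                  cbind(inv[g$edges[, 1]], inv[g$edges[, 2]]))
  })
  res_b <- gspan_mine(db_renumbered, min_support = 3, min_edges = 1,
                      max_edges = 4)
  key_sup <- function(res) {
    s <- vapply(res, `[[`, integer(1), "support")
    names(s) <- vapply(res, `[[`, character(1), "key")
    s[order(names(s))]
  }
  expect_identical(key_sup(res_a), key_sup(res_b))
})

test_that("support is anti-monotone in the subpattern order", {
  set.seed(55)
  db <- lapply(1:8, function(i) random_labeled_graph(6, 0.5))
  res <- gspan_mine(db, min_support = 2, min_edges = 1, max_edges = 4)
  for (p in res) {
    if (p$edge_count < 2) next
    # dropping any edge that keeps the pattern connected cannot lower support
    for (drop in seq_len(p$edge_count)) {
      sub_edges <- p$graph$edges[-drop, , drop = FALSE]
      verts <- sort(unique(as.vector(sub_edges)))
      sub <- labeled_graph(p$graph$labels[verts],
                           matrix(match(as.vector(sub_edges), verts), ncol = 2))
      if (!fcmine:::graph_is_connected(sub)) next
      expect_gte(subgraph_support(sub, db), p$support)
    }
  }
})

test_that("pattern-set comparison is set algebra on canonical keys", {
  db_pre <- list(triangle(), triangle(), triangle())
  db_post <- list(triangle(c("A", "B", "D")), triangle(c("A", "B", "D")),
                  triangle(c("A", "B", "D")))
  pre <- gspan_mine(db_pre, 3, 1, 6)
  post <- gspan_mine(db_post, 3, 1, 6)
  cmp <- compare_frequent_patterns(pre, post)
  expect_true("(0,1,A,-,B)" %in% cmp$persistent)
  expect_true(any(grepl("D", cmp$appeared)))
  expect_true(any(grepl("C", cmp$disappeared)))
  # identical inputs: nothing appears or disappears
  cmp_id <- compare_frequent_patterns(pre, pre)
  expect_length(cmp_id$appeared, 0)
  expect_length(cmp_id$disappeared, 0)
  # empty pre: everything appears
  empty <- gspan_mine(db_pre, 4, 1, 6)
  attr(empty, "min_support") <- 3L
  cmp_empty <- compare_frequent_patterns(empty, post)
  expect_setequal(cmp_empty$appeared,
                  vapply(post, `[[`, character(1), "key"))
  # mismatched parameters are an error
  other <- gspan_mine(db_post, 2, 1, 6)
  expect_error(compare_frequent_patterns(pre, other), "parameters")
})

test_that("gSpan exchange format round-trips", {
  set.seed(66)
  db <- lapply(1:4, function(i) random_labeled_graph(5, 0.5))
  path <- tempfile(fileext = ".txt")
  write_gspan_db(db, path)
  db2 <- read_gspan_db(path)
  expect_equal(length(db2), length(db))
  for (k in seq_along(db)) {
    expect_equal(db2[[k]]$labels, db[[k]]$labels)
    expect_equal(db2[[k]]$edges, db[[k]]$edges, ignore_attr = TRUE)
  }
})
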
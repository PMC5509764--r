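#' Pipeline configuration
#'
#' Bundles every stage's parameters: the synthetic cohort (or the shape of
#' user-supplied data), the sparsity threshold space, the frequent-subgraph
#' mining settings, and the inference settings.
#'
#' @param cohort A [cohort_config()].
#' @param s_min,s_max,s_step Sparsity threshold space (default 5-40% in 1%
#'   steps).
#' @param fsm List of mining settings: `enabled`, `support_fraction`
#'   (fraction of retained subjects a pattern must occur in, default 0.8),
#'   `sparsity` (network density fed to the miner, default 0.10),
#'   `min_edges`, `max_edges` (default 2-6).
#' @param n_perm Permutations for the paired sign-flip tests.
#' @param fdr_family `"all"` (adjust the 3 x N node-metric tests together,
#'   default) or `"per_metric"`.
#' @param alphas Significance / marginal adjusted-p thresholds.
#' @param motion_threshold_mm Motion exclusion threshold (default 2.5 mm).
#' @param rank_by Edge ranking rule for binarization.
#' @param regress_motion Regress the six motion parameters out of each
#'   series before computing correlations (default `TRUE`).
#' @param seed Master seed; the cohort seed and permutation seed are
#'   derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            s_min = 0.05, s_max = 0.40, s_step = 0.01,
                            fsm = list(),
                            n_perm = 10000L,
                            fdr_family = c("all", "per_metric"),
                            alphas = c(0.05, 0.1),
                            motion_threshold_mm = 2.5,
                            rank_by = c("absolute", "positive"),
                            regress_motion = TRUE,
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  fdr_family <- match.arg(fdr_family)
  rank_by <- match.arg(rank_by)
  stopifnot(length(alphas) == 2L, alphas[1] < alphas[2])
  fsm_defaults <- list(enabled = TRUE, support_fraction = 0.8,
                       sparsity = 0.10, min_edges = 2L, max_edges = 6L)
  fsm <- utils::modifyList(fsm_defaults, fsm)
  structure(
    list(cohort = cohort, s_min = s_min, s_max = s_max, s_step = s_step,
         fsm = fsm, n_perm = as.integer(n_perm), fdr_family = fdr_family,
         alphas = alphas, motion_threshold_mm = motion_threshold_mm,
         rank_by = rank_by, regress_motion = isTRUE(regress_motion),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# 32-bit FNV-1a hash of a string, reported as 8 hex digits; used to stamp
# reports with a config fingerprint without external dependencies.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # (h * prime) mod 2^32 in double precision without overflow
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * prime) %% 65536 * 65536 + lo * prime) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

config_fingerprint <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                              digits = NA))
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else if (is.matrix(x)) {
    unclass(x)
  } else {
    x
  }
}

#' Run the full pre/post network analysis pipeline
#'
#' Simulate (or take) a cohort, apply motion-based subject exclusion and
#' initial-volume discarding, regress nuisance signals, build correlation
#' networks over the sparsity threshold space, compute nodal metric AUCs
#' and hubs, mine frequent subgraphs pre and post, and run the inference
#' layer (paired sign-flip permutation tests with BH-FDR on every
#' node-metric AUC, and brain-behavior correlations on the retained
#' subjects). Identical `config` (and cohort) always gives an identical
#' report.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built cohort (e.g. from [generate_cohort()]
#'   or assembled from user data with the same structure); when `NULL` a
#'   synthetic cohort is generated from `config$cohort` with the pipeline
#'   seed.
#' @param out_dir Optional directory; when given, tidy CSVs and a JSON
#'   report are written there.
#' @return Object of class `fcmine_report`; see Details.
#' @details The report contains `cnm` (one row per node-metric test:
#'   observed mean AUC change, direction, raw and adjusted p, significance),
#'   `hubs` (pre/post [detect_hubs()] results on the group-mean degree AUC),
#'   `fsm` (appeared / disappeared / persistent patterns keyed by minimum
#'   DFS code, plus the single-edge appeared/disappeared report),
#'   `correlations` (the [correlation_table()] of metric changes vs score
#'   changes, covariate-residualized), `subjects` (kept/excluded), and
#'   `provenance` (seed, config fingerprint, package version).
#' @export
run_pipeline <- function(config, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    cc <- config$cohort
    cc$seed <- config$seed
    cohort <- generate_cohort(cc)
  }
  stopifnot(inherits(cohort, "synthetic_cohort"))
  labels <- cohort$config$region_labels
  n_nodes <- length(labels)

  ## --- QC: motion exclusion -------------------------------------------
  qc <- apply_motion_exclusion(cohort$motion, config$motion_threshold_mm)
  kept <- qc$kept
  if (length(kept) < 2L) stop("fewer than 2 subjects survive motion exclusion")

  ## --- per-subject networks and metric AUCs ---------------------------
  space <- build_threshold_space(config$s_min, config$s_max, config$s_step)
  motion_by_key <- stats::setNames(
    cohort$motion,
    vapply(cohort$motion, function(m) paste(m$subject_id, m$session), character(1))
  )
  conn <- list()
  for (ts in cohort$timeseries) {
    if (!(ts$subject_id %in% kept)) next
    ts2 <- discard_initial_volumes(ts, cohort$config$n_discard)
    if (config$regress_motion) {
      mt <- motion_by_key[[paste(ts$subject_id, ts$session)]]
      conf <- cbind(mt$translations, mt$rotations)
      if (cohort$config$n_discard > 0) {
        conf <- conf[-seq_len(cohort$config$n_discard), , drop = FALSE]
      }
      ts2 <- regress_confounds(ts2, conf)
    }
    conn[[paste(ts$subject_id, ts$session)]] <- correlation_matrix(ts2)
  }

  auc_arrays <- list(pre = NULL, post = NULL)   # subjects x (metric, node)
  curves_store <- list(pre = list(), post = list())
  test_names <- as.vector(t(outer(metric_names(), labels, paste, sep = ":")))
  for (session in c("pre", "post")) {
    m <- matrix(NA_real_, length(kept), 3L * n_nodes,
                dimnames = list(kept, test_names))
    for (si in seq_along(kept)) {
      curves <- metric_curves(conn[[paste(kept[si], session)]], space,
                              config$rank_by)
      curves_store[[session]][[kept[si]]] <- curves
      for (mi in seq_along(metric_names())) {
        met <- metric_names()[mi]
        vals <- apply(curves[[met]], 1, auc_trapezoid, space = space)
        cols <- (mi - 1L) * n_nodes + seq_len(n_nodes)
        m[si, cols] <- vals
      }
    }
    auc_arrays[[session]] <- m
  }

  ## --- hubs on the group-mean degree AUC ------------------------------
  hubs <- lapply(c(pre = "pre", post = "post"), function(session) {
    deg_cols <- seq_len(n_nodes)
    detect_hubs(colMeans(auc_arrays[[session]][, deg_cols, drop = FALSE]),
                labels = labels)
  })

  ## --- CNM inference ---------------------------------------------------
  perm <- paired_permutation_matrix(auc_arrays$pre, auc_arrays$post,
                                    n_perm = config$n_perm,
                                    seed = derive_seed(config$seed, 1L))
  metric_of <- rep(metric_names(), each = n_nodes)
  if (config$fdr_family == "all") {
    p_adj <- bh_fdr(perm$p_raw)
  } else {
    p_adj <- perm$p_raw
    for (met in metric_names()) {
      idx <- metric_of == met
      p_adj[idx] <- bh_fdr(perm$p_raw[idx])
    }
  }
  cnm <- data.frame(
    node = rep(labels, times = 3L),
    metric = metric_of,
    observed_stat = unname(perm$observed_stat),
    direction = ifelse(perm$observed_stat > 0, "increase",
                       ifelse(perm$observed_stat < 0, "decrease", "none")),
    p_raw = unname(perm$p_raw),
    p_adjusted = unname(p_adj),
    significance = classify_significance(unname(p_adj), config$alphas),
    stringsAsFactors = FALSE
  )

  ## --- FSM arm ---------------------------------------------------------
  fsm_report <- NULL
  if (isTRUE(config$fsm$enabled)) {
    min_support <- max(1L, ceiling(config$fsm$support_fraction * length(kept)))
    dbs <- lapply(c(pre = "pre", post = "post"), function(session) {
      lapply(kept, function(id) {
        labeled_graph_from_network(
          threshold_by_sparsity(conn[[paste(id, session)]],
                                config$fsm$sparsity, config$rank_by)
        )
      })
    })
    mined <- lapply(dbs, gspan_mine, min_support = min_support,
                    min_edges = config$fsm$min_edges,
                    max_edges = config$fsm$max_edges)
    patt_cmp <- compare_frequent_patterns(mined$pre, mined$post)
    edges_pre <- frequent_edges(dbs$pre, min_support)
    edges_post <- frequent_edges(dbs$post, min_support)
    kpre <- paste(edges_pre$from, edges_pre$to, sep = "--")
    kpost <- paste(edges_post$from, edges_post$to, sep = "--")
    fsm_report <- list(
      min_support = min_support, sparsity = config$fsm$sparsity,
      min_edges = config$fsm$min_edges, max_edges = config$fsm$max_edges,
      pre = mined$pre, post = mined$post,
      appeared = patt_cmp$appeared, disappeared = patt_cmp$disappeared,
      persistent = patt_cmp$persistent,
      edges_appeared = setdiff(kpost, kpre),
      edges_disappeared = setdiff(kpre, kpost)
    )
  }

  ## --- brain-behavior correlations -------------------------------------
  correlations <- NULL
  behav <- cohort$behavior
  demo <- cohort$demographics
  if (!is.null(behav) && nrow(behav)) {
    scales <- unique(behav$scale)
    cg_kept <- kept[kept %in% behav$subject_id]
    if (length(cg_kept) >= 4L) {
      delta_scores <- sapply(scales, function(sc) {
        pre <- behav$score[behav$subject_id %in% cg_kept &
                             behav$scale == sc & behav$session == "pre"]
        post <- behav$score[behav$subject_id %in% cg_kept &
                              behav$scale == sc & behav$session == "post"]
        post - pre
      })
      rownames(delta_scores) <- cg_kept
      delta_metrics <- auc_arrays$post[cg_kept, , drop = FALSE] -
        auc_arrays$pre[cg_kept, , drop = FALSE]
      di <- demo[match(cg_kept, demo$subject_id), ]
      resid_fun <- function(v) residualize_covariates(v, di$age, di$sex)
      delta_metrics <- apply(delta_metrics, 2, resid_fun)
      delta_scores <- apply(delta_scores, 2, resid_fun)
      correlations <- correlation_table(delta_metrics, delta_scores,
                                        config$alphas)
    }
  }

  report <- structure(
    list(
      cnm = cnm,
      hubs = hubs,
      fsm = fsm_report,
      correlations = correlations,
      subjects = qc,
      n_tests = nrow(cnm),
      threshold_space = as.numeric(space),
      provenance = list(
        seed = config$seed,
        config_fingerprint = config_fingerprint(config),
        package_version = as.character(utils::packageVersion("fcmine"))
      )
    ),
    class = "fcmine_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Frequent single edges of a graph database
#'
#' Transaction support of every distinct label pair joined by an edge;
#' the edge-level companion of [gspan_mine()] used for the
#' appeared/disappeared connection report.
#'
#' @param db List of [labeled_graph()] transactions.
#' @param min_support Minimum supporting transactions.
#' @return Data frame: from, to (sorted label pair), support.
#' @export
frequent_edges <- function(db, min_support) {
  rows <- lapply(db, function(g) {
    if (nrow(g$edges) == 0L) return(NULL)
    la <- g$labels[g$edges[, 1]]
    lb <- g$labels[g$edges[, 2]]
    swap <- str_less_c(lb, la)
    unique(data.frame(from = ifelse(swap, lb, la), to = ifelse(swap, la, lb),
                      stringsAsFactors = FALSE))
  })
  all_rows <- do.call(rbind, rows)
  if (is.null(all_rows) || nrow(all_rows) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      support = integer(0)))
  }
  tab <- stats::aggregate(list(support = seq_len(nrow(all_rows))),
                          by = list(from = all_rows$from, to = all_rows$to),
                          FUN = length)
  tab <- tab[tab$support >= min_support, , drop = FALSE]
  tab[order(tab$from, tab$to, method = "radix"), , drop = FALSE]
}

#' @export
print.fcmine_report <- function(x, ...) {
  cat("fcmine_report\n")
  cat(sprintf("  subjects: %d kept, %d excluded\n",
              length(x$subjects$kept), length(x$subjects$excluded)))
  cat(sprintf("  CNM: %d node-metric tests, %d significant (adjusted)\n",
              x$n_tests, sum(x$cnm$significance == "significant")))
  cat(sprintf("  hubs: pre {%s} / post {%s}\n",
              paste(x$hubs$pre$hubs, collapse = ", "),
              paste(x$hubs$post$hubs, collapse = ", ")))
  if (!is.null(x$fsm)) {
    cat(sprintf("  FSM: %d pre / %d post patterns; %d appeared, %d disappeared\n",
                length(x$fsm$pre), length(x$fsm$post),
                length(x$fsm$appeared), length(x$fsm$disappeared)))
  }
  if (!is.null(x$correlations)) {
    cat(sprintf("  correlations: %d tested, %d significant, %d marginal\n",
                nrow(x$correlations),
                sum(x$correlations$significance == "significant"),
                sum(x$correlations$significance == "marginal")))
  }
  cat(sprintf("  provenance: seed %d, config %s\n",
              x$provenance$seed, x$provenance$config_fingerprint))
  invisible(x)
}

#' Serialize a report to a JSON string
#'
#' Deterministic (fixed precision-free) JSON rendering of a pipeline
#' report; identical reports give identical strings.
#'
#' @param report An [run_pipeline()] result.
#' @return Length-1 character JSON string.
#' @export
report_to_json <- function(report) {
  x <- unclass(report)
  x$hubs <- lapply(x$hubs, function(h) unclass(h)[c("hubs", "cutoff", "mean", "sd")])
  if (!is.null(x$fsm)) {
    x$fsm$pre <- fsm_patterns_df(x$fsm$pre)
    x$fsm$post <- fsm_patterns_df(x$fsm$post)
  }
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

fsm_patterns_df <- function(patterns) {
  if (length(patterns) == 0L) {
    return(data.frame(key = character(0), support = integer(0),
                      edge_count = integer(0)))
  }
  data.frame(
    key = vapply(patterns, `[[`, character(1), "key"),
    support = vapply(patterns, `[[`, integer(1), "support"),
    edge_count = vapply(patterns, `[[`, integer(1), "edge_count"),
    stringsAsFactors = FALSE
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$cnm, file.path(out_dir, "cnm_tests.csv"),
                   row.names = FALSE)
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations,
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
  }
  writeLines(report_to_json(report), file.path(out_dir, "report.json"))
  invisible(out_dir)
}
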
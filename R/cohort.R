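#' AAL-90 region labels
#'
#' Short names of the 90 cerebral regions of the automated anatomical
#' labeling (AAL) parcellation (45 per hemisphere), in standard atlas order
#' with alternating left/right suffixes (`.L`, `.R`). These are the default
#' node labels of every network produced by the package.
#'
#' @return Character vector of length 90.
#' @export
#' @examples
#' head(aal90_labels())
aal90_labels <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
}

default_region_labels <- function(n_regions) {
  if (n_regions == 90L) aal90_labels() else sprintf("R%03d", seq_len(n_regions))
}

#' Configuration of a synthetic pre/post cohort
#'
#' Describes the statistical world a synthetic resting-state cohort is drawn
#' from: two sessions (pre/post) of multivariate-normal ROI time series with
#' a shared block-modular baseline correlation structure, an injectable
#' post-session connectivity increment on selected nodes, motion traces with
#' a controllable fraction of over-threshold subjects, and behavioral scores
#' linearly coupled to each subject's realized connectivity change.
#'
#' Defaults mirror a typical single-group intervention design: 30 treated
#' subjects scanned twice, 90 AAL regions, 212 volumes of which the first 10
#' are discarded, plus 21 behavioral-only controls.
#'
#' @param n_subjects Number of imaged (treated) subjects.
#' @param n_regions Number of ROIs / network nodes.
#' @param n_volumes Acquired volumes per scan (before discarding).
#' @param n_discard Initial volumes dropped before analysis.
#' @param n_modules Number of blocks in the modular baseline correlation.
#' @param r_within,r_between Baseline correlation within / between modules.
#' @param effect_nodes Integer indices (1-based) of regions whose incident
#'   correlations are incremented in the post session.
#' @param effect_delta Correlation increment applied pre -> post to every
#'   off-diagonal entry touching `effect_nodes` (clipped to a valid range,
#'   matrix repaired to the nearest positive semidefinite correlation).
#' @param behavior_beta Slope coupling a subject's realized mean correlation
#'   change on the affected edges to the post - pre change of each score.
#' @param behavior_noise_sd SD of the Gaussian noise on score changes
#'   (score units).
#' @param motion_exceed_fraction Fraction of subjects (rounded) whose
#'   post-session motion trace exceeds 2.5 mm translation.
#' @param n_controls Number of behavioral-only control subjects.
#' @param region_labels Node labels; defaults to [aal90_labels()] when
#'   `n_regions == 90`.
#' @param seed Integer seed; identical seeds give identical cohorts.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 30L,
                          n_regions = 90L,
                          n_volumes = 212L,
                          n_discard = 10L,
                          n_modules = 5L,
                          r_within = 0.4,
                          r_between = 0.1,
                          effect_nodes = integer(0),
                          effect_delta = 0,
                          behavior_beta = 0,
                          behavior_noise_sd = 1,
                          motion_exceed_fraction = 0,
                          n_controls = 21L,
                          region_labels = NULL,
                          seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_regions <- as.integer(n_regions)
  n_volumes <- as.integer(n_volumes)
  n_discard <- as.integer(n_discard)
  effect_nodes <- as.integer(effect_nodes)
  stopifnot(
    n_subjects >= 1L, n_regions >= 2L,
    n_volumes > n_discard, n_discard >= 0L,
    n_modules >= 1L, n_modules <= n_regions,
    motion_exceed_fraction >= 0, motion_exceed_fraction <= 1,
    behavior_noise_sd >= 0
  )
  if (length(effect_nodes) &&
      (any(effect_nodes < 1L) || any(effect_nodes > n_regions))) {
    stop("effect_nodes must lie within [1, n_regions]")
  }
  if (is.null(region_labels)) region_labels <- default_region_labels(n_regions)
  if (length(region_labels) != n_regions) {
    stop("region_labels must have length n_regions")
  }
  structure(
    list(
      n_subjects = n_subjects, n_regions = n_regions,
      n_volumes = n_volumes, n_discard = n_discard,
      n_modules = as.integer(n_modules),
      r_within = r_within, r_between = r_between,
      effect_nodes = effect_nodes, effect_delta = effect_delta,
      behavior_beta = behavior_beta, behavior_noise_sd = behavior_noise_sd,
      motion_exceed_fraction = motion_exceed_fraction,
      n_controls = as.integer(n_controls),
      region_labels = region_labels,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "cohort_config: %d subjects (+%d controls), %d regions, %d volumes (%d discarded)\n",
    x$n_subjects, x$n_controls, x$n_regions, x$n_volumes, x$n_discard
  ))
  cat(sprintf(
    "  effect: delta=%g on %d node(s); behavior beta=%g, noise sd=%g; motion exceed=%g; seed=%d\n",
    x$effect_delta, length(x$effect_nodes), x$behavior_beta,
    x$behavior_noise_sd, x$motion_exceed_fraction, x$seed
  ))
  invisible(x)
}

#' Block-modular baseline correlation matrix
#'
#' Contiguous blocks of roughly equal size with correlation `r_within`
#' inside a block and `r_between` across blocks; unit diagonal.
#'
#' @param n_regions,n_modules,r_within,r_between See [cohort_config()].
#' @return An `n_regions` x `n_regions` correlation matrix.
#' @export
modular_correlation <- function(n_regions, n_modules = 5L,
                                r_within = 0.4, r_between = 0.1) {
  module <- module_assignment(n_regions, n_modules)
  same <- outer(module, module, "==")
  m <- ifelse(same, r_within, r_between)
  diag(m) <- 1
  m
}

module_assignment <- function(n_regions, n_modules) {
  sort(rep_len(seq_len(n_modules), n_regions))
}

#' Repair a symmetric matrix to the nearest positive semidefinite correlation
#'
#' Eigenvalues are clipped at zero, the matrix reconstructed, and the
#' diagonal rescaled back to one. Off-diagonal magnitudes are capped at
#' 0.999 so the result is always a usable correlation matrix.
#'
#' @param m Symmetric matrix with unit diagonal (possibly indefinite).
#' @return Positive semidefinite correlation matrix.
#' @export
repair_psd_correlation <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (all(vals == 0)) stop("correlation matrix cannot be repaired: all eigenvalues non-positive")
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(r))
  if (any(d <= 0)) stop("correlation matrix cannot be repaired: zero diagonal after eigenvalue clipping")
  r <- r / tcrossprod(d)
  off <- row(r) != col(r)
  r[off] <- pmin(pmax(r[off], -0.999), 0.999)
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Inject a connectivity effect into a correlation matrix
#'
#' Raises every off-diagonal entry touching `effect_nodes` by `delta`
#' (clipped to a valid correlation range) and projects the result back into
#' the set of positive semidefinite correlation matrices by over-relaxed
#' alternating projections between the PSD cone and the affine constraint
#' set (target entries, unit diagonal). For feasible targets this converges
#' to a correlation matrix realizing the increment exactly (to `tol`); for
#' infeasible ones it returns the best attainable compromise and the
#' attained deviation is reported in the `"max_deviation"` attribute.
#'
#' @param sigma Base correlation matrix.
#' @param effect_nodes Indices of affected nodes.
#' @param delta Correlation increment.
#' @param tol Convergence tolerance on the maximum absolute deviation of
#'   the affected entries from their targets.
#' @param max_iter Iteration cap.
#' @param relax Over-relaxation factor in (0, 2).
#' @return Repaired correlation matrix with attribute `max_deviation`.
#' @export
inject_effect_correlation <- function(sigma, effect_nodes, delta,
                                      tol = 1e-4, max_iter = 5000L,
                                      relax = 1.9) {
  p <- nrow(sigma)
  touch <- outer(seq_len(p) %in% effect_nodes,
                 seq_len(p) %in% effect_nodes, "|")
  diag(touch) <- FALSE
  target <- pmin(pmax(sigma[touch] + delta, -0.999), 0.999)
  key <- paste(p, paste(effect_nodes, collapse = ","), delta,
               fnv1a_hash(paste(signif(sigma[touch], 12), collapse = ",")),
               fnv1a_hash(paste(signif(sigma[!touch], 12), collapse = ",")),
               sep = "|")
  cached <- injection_cache[[key]]
  if (!is.null(cached)) return(cached)
  m <- sigma
  dev <- Inf
  for (it in seq_len(max_iter)) {
    cur <- m[touch]
    m[touch] <- cur + relax * (target - cur)
    m <- repair_psd_correlation(m)
    dev <- max(abs(m[touch] - target))
    if (dev < tol) break
  }
  attr(m, "max_deviation") <- dev
  injection_cache[[key]] <- m
  m
}

# memo for repaired effect matrices: the projection is deterministic and
# usually recomputed across many same-structure cohorts (simulation loops)
injection_cache <- new.env(parent = emptyenv())

# Matrix square root via eigendecomposition (Sigma assumed PSD).
matrix_sqrt <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' ROI time-series container
#'
#' @param data Numeric matrix, T timepoints x N regions.
#' @param subject_id Subject identifier.
#' @param session `"pre"` or `"post"`.
#' @param region_labels Column labels (defaults to `colnames(data)`).
#' @return Object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, subject_id, session,
                           region_labels = colnames(data)) {
  data <- as.matrix(data)
  session <- match.arg(session, c("pre", "post"))
  if (is.null(region_labels)) {
    region_labels <- default_region_labels(ncol(data))
  }
  stopifnot(nrow(data) >= 2L, length(region_labels) == ncol(data))
  colnames(data) <- region_labels
  structure(
    list(subject_id = subject_id, session = session,
         data = data, region_labels = region_labels),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("roi_timeseries: subject %s, session %s, %d timepoints x %d regions\n",
              x$subject_id, x$session, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Generate a synthetic pre/post resting-state cohort
#'
#' Draws, for every treated subject, pre- and post-session ROI time series
#' from multivariate normal distributions sharing a block-modular baseline
#' correlation. In the post session every off-diagonal entry touching
#' `effect_nodes` is incremented by `effect_delta` (clipped, then repaired
#' to the nearest positive semidefinite correlation). Behavioral score
#' changes are `behavior_beta` times the subject's realized mean empirical
#' correlation change on the affected edges plus Gaussian noise; controls
#' get pure-noise changes. A chosen number of subjects
#' (`round(motion_exceed_fraction * n_subjects)`) receive a post-session
#' motion trace whose maximum absolute translation exceeds 2.5 mm.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with components
#'   `timeseries` (list of [roi_timeseries()], two per subject),
#'   `motion` (list of motion traces: `subject_id`, `session`,
#'   `translations` T x 3 mm, `rotations` T x 3 rad),
#'   `behavior` (data frame: subject_id, group, session, scale, score),
#'   `demographics` (data frame: subject_id, group, age, sex),
#'   plus the `config` and the pre/post population correlation matrices.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_subjects
  p <- config$n_regions
  labels <- config$region_labels
  subj_ids <- sprintf("sub%03d", seq_len(n))
  ctrl_ids <- if (config$n_controls > 0) {
    sprintf("ctl%03d", seq_len(config$n_controls))
  } else character(0)

  sigma_pre <- modular_correlation(p, config$n_modules,
                                   config$r_within, config$r_between)
  sigma_post <- sigma_pre
  en <- config$effect_nodes
  if (length(en) && config$effect_delta != 0) {
    sigma_post <- inject_effect_correlation(sigma_pre, en, config$effect_delta)
  }
  sq_pre <- matrix_sqrt(sigma_pre)
  sq_post <- matrix_sqrt(sigma_post)

  # pairs (i < j) touching an effect node; used for the behavioral coupling
  eff_pairs <- NULL
  if (length(en)) {
    idx <- which(upper.tri(sigma_pre), arr.ind = TRUE)
    keep <- (idx[, 1] %in% en) | (idx[, 2] %in% en)
    eff_pairs <- idx[keep, , drop = FALSE]
  }

  ts_list <- vector("list", 2L * n)
  motion_list <- vector("list", 2L * n)
  realized_change <- numeric(n)

  n_exceed <- round(config$motion_exceed_fraction * n)
  exceed_subjects <- if (n_exceed > 0) sample(n, n_exceed) else integer(0)

  k <- 1L
  for (s in seq_len(n)) {
    for (session in c("pre", "post")) {
      z <- matrix(stats::rnorm(config$n_volumes * p), config$n_volumes, p)
      sq <- if (session == "pre") sq_pre else sq_post
      x <- z %*% sq
      ts_list[[k]] <- roi_timeseries(x, subj_ids[s], session, labels)
      motion_list[[k]] <- simulate_motion_trace(
        subj_ids[s], session, config$n_volumes,
        exceed = (session == "post" && s %in% exceed_subjects)
      )
      k <- k + 1L
    }
    if (!is.null(eff_pairs)) {
      analyzed <- function(m) {
        if (config$n_discard > 0) m[-seq_len(config$n_discard), , drop = FALSE] else m
      }
      c_pre <- stats::cor(analyzed(ts_list[[k - 2L]]$data))
      c_post <- stats::cor(analyzed(ts_list[[k - 1L]]$data))
      realized_change[s] <- mean(c_post[eff_pairs] - c_pre[eff_pairs])
    }
  }

  behavior <- simulate_behavior(config, subj_ids, ctrl_ids, realized_change)
  demographics <- simulate_demographics(subj_ids, ctrl_ids)

  structure(
    list(
      timeseries = ts_list,
      motion = motion_list,
      behavior = behavior$scores,
      demographics = demographics,
      realized_change = stats::setNames(realized_change, subj_ids),
      sigma_pre = sigma_pre,
      sigma_post = sigma_post,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

# Behavioral scales and plausible baseline distributions. Full-scale
# quotients are on an IQ-like scale (mean ~120 in this population), the
# subtests on the Wechsler scaled-score scale.
behavior_scales <- function() {
  list(
    FIQ = c(mean = 120, sd = 9),
    MQ = c(mean = 120, sd = 10),
    Associate = c(mean = 10, sd = 3),
    `Visual Reproduction` = c(mean = 10, sd = 3),
    `Block Design` = c(mean = 10, sd = 3),
    `Picture Completion` = c(mean = 10, sd = 3)
  )
}

simulate_behavior <- function(config, subj_ids, ctrl_ids, realized_change) {
  scales <- behavior_scales()
  rows <- list()
  add <- function(id, group, scale, pre, post) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = id, group = group,
      session = c("pre", "post"), scale = scale,
      score = c(pre, post), stringsAsFactors = FALSE
    )
  }
  for (s in seq_along(subj_ids)) {
    for (nm in names(scales)) {
      pre <- stats::rnorm(1, scales[[nm]]["mean"], scales[[nm]]["sd"])
      delta <- config$behavior_beta * realized_change[s] +
        stats::rnorm(1, 0, config$behavior_noise_sd)
      add(subj_ids[s], "CG", nm, pre, pre + delta)
    }
  }
  for (id in ctrl_ids) {
    for (nm in names(scales)) {
      pre <- stats::rnorm(1, scales[[nm]]["mean"], scales[[nm]]["sd"])
      add(id, "control", nm, pre, pre + stats::rnorm(1, 0, config$behavior_noise_sd))
    }
  }
  list(scores = do.call(rbind, rows))
}

simulate_demographics <- function(subj_ids, ctrl_ids) {
  all_ids <- c(subj_ids, ctrl_ids)
  n <- length(all_ids)
  data.frame(
    subject_id = all_ids,
    group = c(rep("CG", length(subj_ids)), rep("control", length(ctrl_ids))),
    age = round(stats::runif(n, 20, 50)),
    sex = ifelse(stats::runif(n) < 0.2, "M", "F"),
    stringsAsFactors = FALSE
  )
}

# Slow drift plus jitter; `exceed` rescales translations so the maximum
# absolute excursion lands above the 2.5 mm exclusion threshold.
simulate_motion_trace <- function(subject_id, session, n_volumes, exceed = FALSE) {
  drift <- apply(matrix(stats::rnorm(n_volumes * 3, sd = 0.02), n_volumes, 3), 2, cumsum)
  translations <- drift + matrix(stats::rnorm(n_volumes * 3, sd = 0.05), n_volumes, 3)
  rotations <- apply(matrix(stats::rnorm(n_volumes * 3, sd = 2e-4), n_volumes, 3), 2, cumsum)
  if (exceed) {
    target <- stats::runif(1, 2.6, 3.5)
    translations <- translations * (target / max(abs(translations)))
  } else {
    cap <- max(abs(translations))
    if (cap > 2.0) translations <- translations * (2.0 / cap)
  }
  colnames(translations) <- c("tx", "ty", "tz")
  colnames(rotations) <- c("rx", "ry", "rz")
  list(subject_id = subject_id, session = session,
       translations = translations, rotations = rotations)
}

#' Discard initial volumes of a time series
#'
#' Scanner signal is unstable over the first volumes of a resting-state
#' acquisition; they are removed before any analysis.
#'
#' @param ts A [roi_timeseries()].
#' @param n_discard Number of initial rows (volumes) to drop.
#' @return The trimmed `roi_timeseries` (T' = T - n_discard).
#' @export
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(212 * 4), 212, 4), "s1", "pre")
#' nrow(discard_initial_volumes(ts, 10)$data)  # 202
discard_initial_volumes <- function(ts, n_discard) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) stop("n_discard must be non-negative")
  if (n_discard >= nrow(ts$data)) {
    stop(sprintf("cannot discard %d volumes from a %d-volume series",
                 n_discard, nrow(ts$data)))
  }
  if (n_discard == 0L) return(ts)
  ts$data <- ts$data[-seq_len(n_discard), , drop = FALSE]
  ts
}

#' Motion-based subject exclusion
#'
#' A subject is excluded when, in any of its sessions, the maximum absolute
#' head translation over timepoints and axes exceeds `threshold_mm`
#' (strictly greater than; a subject exactly at the threshold is kept).
#' Rotations are not part of the rule.
#'
#' @param traces List of motion traces (as produced by [generate_cohort()]):
#'   each a list with `subject_id`, `session`, `translations` (T x 3 mm).
#' @param threshold_mm Exclusion threshold in millimetres (default 2.5).
#' @return List with character vectors `kept` and `excluded` (disjoint,
#'   exhaustive over the subjects present in `traces`).
#' @export
apply_motion_exclusion <- function(traces, threshold_mm = 2.5) {
  stopifnot(threshold_mm > 0)
  if (length(traces) == 0L) return(list(kept = character(0), excluded = character(0)))
  ids <- vapply(traces, function(tr) as.character(tr$subject_id), character(1))
  peak <- vapply(traces, function(tr) max(abs(tr$translations)), numeric(1))
  subj <- unique(ids)
  worst <- vapply(subj, function(s) max(peak[ids == s]), numeric(1))
  list(
    kept = subj[worst <= threshold_mm],
    excluded = subj[worst > threshold_mm]
  )
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
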
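#' Residualize a measure on age and sex
#'
#' Least-squares residuals of a per-subject vector against an intercept,
#' age, and a sex indicator, removing demographic influence before
#' correlation analyses. Residuals sum to zero and are orthogonal to both
#' covariates.
#'
#' @param values Numeric vector, one value per subject.
#' @param age Numeric vector of ages (years).
#' @param sex Character/factor vector (`"M"`/`"F"` or any two levels).
#' @return Numeric residual vector.
#' @export
residualize_covariates <- function(values, age, sex) {
  n <- length(values)
  stopifnot(length(age) == n, length(sex) == n, n >= 4L)
  age <- as.numeric(age)
  sex_num <- as.numeric(factor(sex))
  design <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if (stats::sd(age) > 0) design <- cbind(design, age = age)
  if (stats::sd(sex_num) > 0) design <- cbind(design, sex = sex_num)
  if (ncol(design) == 1L) {
    stop("covariate design is rank deficient: constant age in a single-sex sample")
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    stop("covariate design is rank deficient (age collinear with sex)")
  }
  as.numeric(qr.resid(qr_d, values))
}

#' Paired sign-flip permutation test
#'
#' Within-subject pre/post comparison: the statistic is the mean of the
#' paired differences `post - pre`, and the null distribution is generated
#' by independently flipping the sign of each subject's difference. The
#' two-sided p-value uses the add-one estimator
#' `(1 + #{|null| >= |observed|}) / (1 + n_perm)` so it can never be zero.
#'
#' @param pre,post Numeric vectors of equal length (>= 2 pairs).
#' @param n_perm Number of random sign patterns (default 10000).
#' @param seed Integer seed for the sign patterns.
#' @return List with `observed_stat`, `p_raw`, `n_permutations`, `seed`.
#' @export
paired_permutation_test <- function(pre, post, n_perm = 10000L, seed = 1L) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L, n_perm >= 1L)
  d <- post - pre
  obs <- mean(d)
  if (all(d == 0)) {
    return(list(observed_stat = 0, p_raw = 1,
                n_permutations = as.integer(n_perm), seed = as.integer(seed)))
  }
  null_stats <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                    n_perm, length(d))
    as.numeric(signs %*% d) / length(d)
  })
  tol <- 1e-12 * max(1, abs(obs))
  p <- (1 + sum(abs(null_stats) >= abs(obs) - tol)) / (1 + n_perm)
  list(observed_stat = obs, p_raw = p,
       n_permutations = as.integer(n_perm), seed = as.integer(seed))
}

# Vectorized sign-flip test over the columns of paired matrices
# (subjects x tests); one shared set of sign patterns across tests.
paired_permutation_matrix <- function(pre, post, n_perm = 10000L, seed = 1L) {
  stopifnot(all(dim(pre) == dim(post)), nrow(pre) >= 2L)
  d <- post - pre
  obs <- colMeans(d)
  null_stats <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * nrow(d), replace = TRUE),
                    n_perm, nrow(d))
    (signs %*% d) / nrow(d)
  })
  tol <- 1e-12 * pmax(1, abs(obs))
  exceed <- colSums(abs(null_stats) >= rep(abs(obs) - tol, each = n_perm))
  p <- (1 + exceed) / (1 + n_perm)
  p[colSums(d != 0) == 0L] <- 1
  list(observed_stat = obs, p_raw = p, n_permutations = as.integer(n_perm),
       seed = as.integer(seed))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: with the m raw p-values sorted ascending,
#' `adj_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and returned in the
#' input order.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  adj_sorted <- rev(cummin(rev(p_values[ord] * m / seq_len(m))))
  pmin(adj_sorted, 1)[order(ord)]
}

#' Cohen's d from a correlation coefficient
#'
#' Converts a Pearson correlation into the standardized effect size
#' `d = 2|r| / sqrt(1 - r^2)` (always non-negative; the sign of the
#' association is carried by r itself).
#'
#' @param r Correlation value(s), `|r| < 1`.
#' @return Cohen's d, same length as `r`.
#' @export
#' @examples
#' round(effect_size_from_r(0.523), 3)  # 1.227
effect_size_from_r <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be strictly less than 1")
  2 * abs(r) / sqrt(1 - r^2)
}

#' Correlation between a metric change and a cognition change
#'
#' Pearson correlation of per-subject changes (post - pre) in a nodal
#' metric's AUC with changes in a cognitive score, with the two-sided
#' p-value from the exact t transform `t = r sqrt(n-2) / sqrt(1-r^2)` and
#' the attached Cohen's d. Family-wise FDR adjustment and significance
#' labeling happen across the whole tested family (see
#' [correlation_table()]).
#'
#' @param delta_metric,delta_score Numeric vectors of per-subject changes.
#' @param metric,node,scale Optional identifiers stored in the result.
#' @return List with `r`, `p_raw`, `effect_size_d`, `n` and the
#'   identifiers. A perfect correlation yields `effect_size_d = Inf` with a
#'   warning.
#' @export
metric_cognition_correlation <- function(delta_metric, delta_score,
                                         metric = NA_character_,
                                         node = NA_character_,
                                         scale = NA_character_) {
  n <- length(delta_metric)
  stopifnot(length(delta_score) == n, n >= 3L)
  if (stats::sd(delta_metric) == 0 || stats::sd(delta_score) == 0) {
    stop("constant input: correlation undefined")
  }
  r <- stats::cor(delta_metric, delta_score)
  if (abs(r) >= 1 - 1e-15) {
    warning("degenerate (perfect) correlation; effect size is infinite")
    d <- Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    d <- effect_size_from_r(r)
  }
  list(metric = metric, node = node, scale = scale,
       r = r, p_raw = p, effect_size_d = d, n = n)
}

#' Brain-behavior correlation table with FDR and significance labels
#'
#' Computes [metric_cognition_correlation()] for every column pair of a
#' metric-change matrix and a score-change matrix, adjusts the whole family
#' with [bh_fdr()], converts each r to Cohen's d, and labels each row
#' significant (adjusted p < alpha[1]), marginal (adjusted p < alpha[2]) or
#' none.
#'
#' @param delta_metrics Numeric matrix, subjects x (node-metric) columns;
#'   column names identify the tests.
#' @param delta_scores Numeric matrix, subjects x scales.
#' @param alphas Significance / marginal thresholds (default 0.05, 0.1).
#' @return Data frame: test, scale, r, p_raw, p_adjusted, effect_size_d, n,
#'   significance.
#' @export
correlation_table <- function(delta_metrics, delta_scores,
                              alphas = c(0.05, 0.1)) {
  delta_metrics <- as.matrix(delta_metrics)
  delta_scores <- as.matrix(delta_scores)
  stopifnot(nrow(delta_metrics) == nrow(delta_scores))
  n <- nrow(delta_metrics)
  grid <- expand.grid(test = seq_len(ncol(delta_metrics)),
                      scale = seq_len(ncol(delta_scores)))
  r <- mapply(function(a, b) stats::cor(delta_metrics[, a], delta_scores[, b]),
              grid$test, grid$scale)
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p_raw <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p_adj <- bh_fdr(p_raw)
  data.frame(
    test = colnames(delta_metrics)[grid$test],
    scale = colnames(delta_scores)[grid$scale],
    r = r, p_raw = p_raw, p_adjusted = p_adj,
    effect_size_d = effect_size_from_r(r), n = n,
    significance = classify_significance(p_adj, alphas),
    stringsAsFactors = FALSE
  )
}

#' Pooled-variance two-sample t-test from group summaries
#'
#' The classic independent-samples t-test computed directly from printed
#' group summaries (means, SDs, sizes), as reported in demographic tables:
#' `t = (m1 - m2) / (s_p sqrt(1/n1 + 1/n2))` with
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @seealso [two_sample_t_raw()] for raw data.
#' @export
#' @examples
#' round(two_sample_t(120.833, 9.021, 30, 118.333, 8.924, 21)$t, 3)  # 0.978
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2L, n2 >= 2L, sd1 > 0 || sd2 > 0, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df = df))
}

#' @rdname two_sample_t
#' @param x,y Raw observation vectors of the two groups.
#' @export
two_sample_t_raw <- function(x, y) {
  two_sample_t(mean(x), stats::sd(x), length(x),
               mean(y), stats::sd(y), length(y))
}

#' Levene's test for equality of variances
#'
#' Classic (mean-centered) Levene test: a one-way ANOVA on the absolute
#' deviations of each observation from its group center.
#'
#' @param group1,group2 Raw observation vectors.
#' @param center `"mean"` (classic Levene, default) or `"median"`
#'   (Brown-Forsythe).
#' @return List with `F`, `df` (c(1, n-2)), `p`.
#' @export
levene_test <- function(group1, group2, center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  cf <- if (center == "mean") mean else stats::median
  z1 <- abs(group1 - cf(group1))
  z2 <- abs(group2 - cf(group2))
  z <- c(z1, z2)
  g <- rep(1:2, c(length(z1), length(z2)))
  n <- length(z)
  zbar <- mean(z)
  means <- tapply(z, g, mean)
  ss_between <- sum(tabulate(g) * (means - zbar)^2)
  ss_within <- sum((z - means[g])^2)
  df2 <- n - 2L
  f_stat <- (ss_between / 1) / (ss_within / df2)
  list(F = f_stat, df = c(1L, df2),
       p = stats::pf(f_stat, 1, df2, lower.tail = FALSE))
}

#' Two-way between-subjects ANOVA (Treatment x Time)
#'
#' Type-II sums of squares for the 2 x 2 layout with interaction, the
#' design used to test whether a treated group improves over time relative
#' to controls.
#'
#' @param scores Numeric response vector.
#' @param treatment Factor/character with two levels (e.g. CG vs control).
#' @param time Factor/character with two levels (pre vs post).
#' @return Data frame with rows Treatment, Time, Treatment:Time and columns
#'   df, sumsq, F, p.
#' @export
two_way_anova <- function(scores, treatment, time) {
  treatment <- factor(treatment)
  time <- factor(time)
  stopifnot(length(scores) == length(treatment),
            length(scores) == length(time))
  cells <- table(treatment, time)
  if (any(cells < 2L)) stop("every Treatment x Time cell needs >= 2 observations")
  rss <- function(fml) sum(stats::residuals(stats::lm(fml))^2)
  rss_full <- rss(scores ~ treatment * time)
  rss_ab <- rss(scores ~ treatment + time)
  rss_a <- rss(scores ~ treatment)
  rss_b <- rss(scores ~ time)
  df_resid <- length(scores) - 4L
  mse <- rss_full / df_resid
  ss <- c(Treatment = rss_b - rss_ab, Time = rss_a - rss_ab,
          `Treatment:Time` = rss_ab - rss_full)
  f_stat <- ss / mse
  data.frame(
    term = names(ss), df = 1L, sumsq = unname(ss), F = unname(f_stat),
    p = stats::pf(unname(f_stat), 1, df_resid, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Classify an adjusted p-value
#'
#' Strict-inequality convention: `significant` if adjusted p < alphas[1],
#' `marginal` if alphas[1] <= p < alphas[2], otherwise `none` (so exactly
#' 0.05 is marginal, not significant).
#'
#' @param p_adjusted Numeric vector of adjusted p-values.
#' @param alphas Thresholds, default `c(0.05, 0.1)`.
#' @return Character vector: `"significant"`, `"marginal"` or `"none"`.
#' @export
classify_significance <- function(p_adjusted, alphas = c(0.05, 0.1)) {
  stopifnot(length(alphas) == 2L, alphas[1] < alphas[2])
  ifelse(p_adjusted < alphas[1], "significant",
         ifelse(p_adjusted < alphas[2], "marginal", "none"))
}
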
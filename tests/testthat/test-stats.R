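test_that("covariate residualization is exact least squares", {
  set.seed(1)
  n <- 1000
  age <- runif(n, 20, 55)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  # values independent of age/sex: residuals approach the centered values
  v <- rnorm(n)
  res <- residualize_covariates(v, age, sex)
  expect_lt(max(abs(res - (v - mean(v)))), 0.1)
  expect_lt(abs(sum(res)), 1e-8)
  # perfect fit is annihilated
  expect_lt(max(abs(residualize_covariates(2 * age, age, sex))), 1e-8)
  # residuals orthogonal to the design
  v2 <- rnorm(30)
  r2 <- residualize_covariates(v2, age[1:30], sex[1:30])
  expect_lt(abs(sum(r2 * age[1:30])), 1e-7)
  expect_lt(abs(sum(r2 * (sex[1:30] == "M"))), 1e-8)
  # single-sex + constant age is rank deficient
  expect_error(residualize_covariates(v2, rep(30, 30), rep("F", 30)),
               "rank")
})

test_that("sign-flip permutation p agrees with exhaustive enumeration", {
  set.seed(2)
  for (rep in 1:5) {
    d <- rnorm(5, mean = 0.6)
    pre <- rnorm(5)
    post <- pre + d
    exact <- oracle_exact_signflip_p(d)
    mc <- paired_permutation_test(pre, post, n_perm = 4000, seed = rep)
    # binomial Monte-Carlo error around the exact enumeration value
    se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(mc$p_raw - exact), 4 * se + 2 / 4000)
    expect_equal(mc$observed_stat, mean(d))
  }
  # all-zero differences: p = 1 by convention
  x <- rnorm(6)
  expect_equal(paired_permutation_test(x, x, 100, 1)$p_raw, 1)
  # determinism under a fixed seed
  pre2 <- rnorm(8); post2 <- pre2 + rnorm(8, 0.4)
  expect_identical(paired_permutation_test(pre2, post2, 500, 99),
                   paired_permutation_test(pre2, post2, 500, 99))
})

test_that("vectorized permutation matches the single-column test", {
  set.seed(3)
  pre <- matrix(rnorm(10 * 4), 10, 4)
  post <- pre + matrix(rnorm(10 * 4, 0.3), 10, 4)
  multi <- paired_permutation_matrix(pre, post, n_perm = 500, seed = 7)
  for (k in 1:4) {
    single <- paired_permutation_test(pre[, k], post[, k],
                                      n_perm = 500, seed = 7)
    expect_equal(multi$observed_stat[k], single$observed_stat)
  }
  expect_true(all(multi$p_raw > 0 & multi$p_raw <= 1))
})

test_that("BH step-up adjustment matches hand and reference computations", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)  # single p unchanged
  set.seed(4)
  for (rep in 1:50) {
    p <- runif(sample(3:200, 1))
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in sorted order
    expect_lt(max(abs(adj - stats::p.adjust(p, method = "BH"))), 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 0)), "p-values")
  expect_error(bh_fdr(c(0.1, 1.2)), "p-values")
})

test_that("r-to-d conversion reproduces all printed effect sizes", {
  # the 11 (r, d) pairs of the brain-behavior correlation table
  r <- c(0.402, -0.381, 0.350, -0.427, -0.357, 0.364, 0.350, -0.413,
         0.523, -0.333, -0.385)
  d <- c(0.878, 0.824, 0.747, 0.944, 0.764, 0.782, 0.747, 0.907,
         1.227, 0.706, 0.834)
  expect_equal(round(effect_size_from_r(r), 3), d)
  expect_equal(effect_size_from_r(0), 0)
  expect_error(effect_size_from_r(1), "strictly less")
})

test_that("metric-cognition correlation has exact t-based p-values", {
  set.seed(5)
  x <- rnorm(26)
  y <- 0.5 * x + rnorm(26, sd = 1)
  res <- metric_cognition_correlation(x, y, "degree", "INS.L", "FIQ")
  ct <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p_raw, ct$p.value)
  expect_equal(res$n, 26)
  expect_equal(res$effect_size_d, effect_size_from_r(res$r))
  # perfect linear relation is flagged as degenerate
  expect_warning(res2 <- metric_cognition_correlation(x, 3 * x), "degenerate")
  expect_equal(res2$r, 1)
  expect_equal(res2$effect_size_d, Inf)
  expect_error(metric_cognition_correlation(rep(1, 10), rnorm(10)),
               "constant")
})

test_that("null correlations at n = 26 exceed 0.388 about 5% of the time", {
  # |r| for independent normals: P(|r| > r_crit) = 0.05 at n = 26 when
  # r_crit satisfies the t transform with df = 24
  set.seed(6)
  n_rep <- 4000
  hits <- vapply(seq_len(n_rep), function(i) {
    abs(stats::cor(rnorm(26), rnorm(26))) > 0.388
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.015)
})

test_that("behavioral coupling is recovered by the correlation stage", {
  # generator with behavior_beta > 0: the realized metric change correlates
  # with the score change at the strength implied by the noise level
  r_vals <- vapply(1:20, function(k) {
    cc <- cohort_config(n_subjects = 26, n_regions = 20, n_volumes = 80,
                        n_discard = 0, n_modules = 4,
                        effect_nodes = c(2, 12), effect_delta = 0.2,
                        behavior_beta = 40, behavior_noise_sd = 1,
                        n_controls = 0, seed = 300 + k)
    co <- generate_cohort(cc)
    dscore <- with(co$behavior[co$behavior$scale == "FIQ", ],
                   score[session == "post"] - score[session == "pre"])
    stats::cor(co$realized_change, dscore)
  }, numeric(1))
  expect_gt(mean(r_vals), 0.3)  # clearly positive coupling on average
})

test_that("pooled-variance t reproduces the printed intake comparisons", {
  fiq <- two_sample_t(120.833, 9.021, 30, 118.333, 8.924, 21)
  expect_equal(round(fiq$t, 3), 0.978)
  expect_equal(fiq$df, 49)
  mq <- two_sample_t(120.367, 9.967, 30, 118.600, 14.080, 20)
  expect_equal(round(mq$t, 3), 0.520)
  expect_equal(mq$df, 48)
  expect_equal(two_sample_t(5, 1, 10, 5, 1, 10)$t, 0)
  # summary form equals raw-data form when summaries come from the data
  set.seed(7)
  x <- rnorm(30, 120, 9); y <- rnorm(21, 118, 9)
  raw <- two_sample_t_raw(x, y)
  summ <- two_sample_t(mean(x), sd(x), 30, mean(y), sd(y), 21)
  expect_equal(raw$t, summ$t)
  expect_equal(raw$p, summ$p)
  # cross-check against the reference implementation
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(raw$t, unname(ref$statistic))
  expect_equal(raw$p, ref$p.value)
})

test_that("Levene test detects unequal spread and not shifts", {
  set.seed(8)
  g1 <- rnorm(30)
  lev_shift <- levene_test(g1, g1 + 5)
  expect_lt(lev_shift$F, 1e-20)       # pure shift: identical deviations
  lev_scale <- levene_test(g1, 3 * (g1 - mean(g1)))
  expect_lt(lev_scale$p, 0.01)        # tripled spread at n = 30
})

test_that("two-way ANOVA recovers designed effects", {
  set.seed(9)
  trt <- rep(c("CG", "control"), each = 40)
  time <- rep(rep(c("pre", "post"), each = 20), 2)
  # all cell means equal: every F is near zero on average; exact zero with
  # zero-noise response
  flat <- two_way_anova(rep(5, 80), trt, time)
  expect_true(all(flat$sumsq < 1e-20))
  # constructed crossing interaction dominates
  y <- ifelse(trt == "CG", 1, -1) * ifelse(time == "post", 1, -1) +
    rnorm(80, sd = 0.3)
  tab <- two_way_anova(y, trt, time)
  expect_equal(tab$term, c("Treatment", "Time", "Treatment:Time"))
  expect_gt(tab$F[3], tab$F[1])
  expect_gt(tab$F[3], tab$F[2])
  expect_lt(tab$p[3], 1e-6)
  # matches the reference type-II computation on balanced data
  ref <- stats::anova(stats::lm(y ~ factor(trt) * factor(time)))
  expect_equal(tab$F, ref$`F value`[1:3], tolerance = 1e-10)
  expect_error(two_way_anova(rnorm(3), c("a", "a", "b"),
                             c("pre", "post", "pre")), "cell")
})

test_that("significance classification follows the strict-< convention", {
  expect_equal(classify_significance(c(0.020, 0.071, 0.05, 0.049999, 0.2)),
               c("significant", "marginal", "marginal", "significant", "none"))
})
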
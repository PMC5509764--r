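small_config <- function(...) {
  cohort_config(n_subjects = 4, n_regions = 12, n_volumes = 60,
                n_discard = 5, n_modules = 3, n_controls = 3, seed = 11, ...)
}

test_that("identical config and seed give byte-identical cohorts", {
  cc <- small_config(effect_nodes = c(1, 7), effect_delta = 0.2,
                     behavior_beta = 5, motion_exceed_fraction = 0.25)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # a different seed actually changes the draw
  cc2 <- cc; cc2$seed <- 12L
  expect_false(identical(generate_cohort(cc2)$timeseries[[1]]$data,
                         a$timeseries[[1]]$data))
})

test_that("generated cohorts have the declared structure", {
  cc <- small_config(motion_exceed_fraction = 0.5)
  co <- generate_cohort(cc)
  expect_length(co$timeseries, 2 * cc$n_subjects)
  for (ts in co$timeseries) {
    expect_equal(dim(ts$data), c(cc$n_volumes, cc$n_regions))
    expect_true(all(apply(ts$data, 2, stats::sd) > 0))  # no constant column
  }
  # exactly round(fraction * n) subjects exceed 2.5 mm, in the post session
  peaks <- vapply(co$motion, function(m) max(abs(m$translations)), numeric(1))
  sessions <- vapply(co$motion, `[[`, character(1), "session")
  expect_equal(sum(peaks > 2.5), round(0.5 * cc$n_subjects))
  expect_true(all(sessions[peaks > 2.5] == "post"))
  # behavior: one row per subject x session x scale, finite scores
  behav <- co$behavior
  expect_false(any(duplicated(behav[c("subject_id", "session", "scale")])))
  expect_true(all(is.finite(behav$score)))
  expect_setequal(unique(behav$group), c("CG", "control"))
})

test_that("empirical correlations converge to the target structure", {
  cc <- cohort_config(n_subjects = 1, n_regions = 15, n_volumes = 10010,
                      n_discard = 10, n_modules = 3, n_controls = 0, seed = 3)
  co <- generate_cohort(cc)
  emp <- stats::cor(co$timeseries[[1]]$data[-(1:10), ])
  expect_lt(max(abs(emp - co$sigma_pre)), 0.05)
})

test_that("injected connectivity effect is realized (Monte-Carlo)", {
  # delta = 0.3 on 2 nodes, 30 subjects, 50 cohorts: the mean empirical
  # pre -> post correlation increase on the affected edges recovers the
  # injected increment
  deltas <- vapply(1:50, function(k) {
    cc <- cohort_config(n_subjects = 30, effect_nodes = c(5, 50),
                        effect_delta = 0.3, n_controls = 0, seed = 1000 + k)
    mean(generate_cohort(cc)$realized_change)
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 0.3), 0.05)
})

test_that("null cohorts give nominal false-positive rates downstream", {
  # effect_delta = 0, behavior_beta = 0: the paired sign-flip test on a
  # node's degree AUC rejects at about the nominal 5% over repeated cohorts
  space <- build_threshold_space(0.2, 0.4, 0.1)
  reject <- vapply(1:200, function(k) {
    cc <- cohort_config(n_subjects = 12, n_regions = 10, n_volumes = 40,
                        n_discard = 0, n_modules = 2, n_controls = 0,
                        seed = 5000 + k)
    co <- generate_cohort(cc)
    auc_by_session <- sapply(c("pre", "post"), function(sess) {
      vapply(co$timeseries[vapply(co$timeseries, `[[`, character(1),
                                  "session") == sess],
             function(ts) {
               curves <- metric_curves(correlation_matrix(ts), space)
               auc_trapezoid(curves$degree[1, ], space)
             }, numeric(1))
    })
    paired_permutation_test(auc_by_session[, "pre"], auc_by_session[, "post"],
                            n_perm = 199, seed = k)$p_raw <= 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.01)
  expect_lt(mean(reject), 0.10)
})

test_that("initial-volume discarding matches the acquisition design", {
  ts <- roi_timeseries(matrix(rnorm(212 * 4), 212, 4), "s1", "pre")
  expect_equal(nrow(discard_initial_volumes(ts, 10)$data), 202)
  expect_identical(discard_initial_volumes(ts, 0), ts)
  short <- roi_timeseries(matrix(rnorm(5 * 3), 5, 3), "s1", "pre")
  expect_error(discard_initial_volumes(short, 5), "discard")
  # content check: remaining rows are the original tail
  expect_equal(discard_initial_volumes(ts, 10)$data, ts$data[11:212, ])
})

test_that("motion exclusion uses strict > 2.5 mm on any session", {
  trace <- function(id, session, peak) {
    tr <- matrix(0.1, 20, 3)
    tr[7, 2] <- peak
    list(subject_id = id, session = session, translations = tr,
         rotations = matrix(0, 20, 3))
  }
  traces <- list(trace("a", "pre", 0.5), trace("a", "post", 2.6),
                 trace("b", "pre", 2.5), trace("b", "post", 1.0),
                 trace("c", "pre", 0.3), trace("c", "post", 0.3))
  part <- apply_motion_exclusion(traces)
  expect_setequal(part$excluded, "a")         # 2.6 mm in one session
  expect_setequal(part$kept, c("b", "c"))     # 2.5 mm exactly is kept
  # exhaustive + disjoint, invariant to trace order
  expect_setequal(c(part$kept, part$excluded), c("a", "b", "c"))
  part2 <- apply_motion_exclusion(rev(traces))
  expect_setequal(part2$kept, part$kept)
  expect_setequal(part2$excluded, part$excluded)
  expect_equal(apply_motion_exclusion(list()),
               list(kept = character(0), excluded = character(0)))
})

test_that("a 29-subject cohort with 3 over-threshold scans keeps 26", {
  cc <- cohort_config(n_subjects = 29, n_regions = 5, n_volumes = 20,
                      n_discard = 0, n_modules = 1, n_controls = 0,
                      motion_exceed_fraction = 3 / 29, seed = 8)
  co <- generate_cohort(cc)
  part <- apply_motion_exclusion(co$motion)
  expect_length(part$excluded, 3)
  expect_length(part$kept, 26)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_volumes = 10, n_discard = 10))
  expect_error(cohort_config(motion_exceed_fraction = 1.5))
  expect_error(cohort_config(effect_nodes = c(0, 3)), "effect_nodes")
  expect_error(cohort_config(effect_nodes = 91), "effect_nodes")
})
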
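# balanced repeated-measures fixture: n subjects x 2 scans, scanner per scan
make_long_ft <- function(y, scanner_per_scan, n_sub, days = c(0, 400)) {
  rec <- make_records(rep(paste0("s", seq_len(n_sub)), each = 2),
                      paste0("sc", seq_len(2 * n_sub)),
                      scanner = scanner_per_scan,
                      day = rep(days, n_sub))
  m <- matrix(y, nrow = 1,
              dimnames = list("volume__r", rec$scan_id))
  ft_from_matrix(rec, m)
}

test_that("known scanner offset is recovered exactly at zero noise", {
  set.seed(41)
  n <- 20
  subj <- rep(rnorm(n, 0, 3), each = 2)
  scanner <- rep(c(1L, 2L), n)              # each subject scanned on both
  y <- 100 + subj + 5 * (scanner == 2L)
  ft <- make_long_ft(y, scanner, n)
  fit <- suppressWarnings(
    fit_feature_lmm(ft, "volume__r", ranef = "intercept_only"))
  expect_equal(unname(diff(fit$gamma_raw)), 5, tolerance = 1e-6)
  # weighted sum-to-zero constraint on the offsets
  expect_equal(sum(as.numeric(fit$n_i) * fit$gamma_raw), 0, tolerance = 1e-8)
})

test_that("zero subject variance lands on the boundary with a warning-free fit", {
  set.seed(43)
  n <- 30
  scanner <- rep(c(1L, 2L), n)
  y <- 100 + rnorm(2 * n)                   # no subject effect at all
  ft <- make_long_ft(y, scanner, n)
  fit <- suppressWarnings(
    fit_feature_lmm(ft, "volume__r", ranef = "intercept_only"))
  expect_lt(fit$varcomp["subject_intercept"], 0.2)
  expect_true(fit$singular || fit$varcomp["subject_intercept"] >= 0)
})

test_that("variance components are recovered within 15%", {
  set.seed(47)
  n <- 100
  k <- 3
  rec <- make_records(rep(paste0("s", 1:n), each = k),
                      paste0("sc", seq_len(n * k)),
                      scanner = rep_len(c(1L, 2L, 1L), n * k),
                      day = rep(c(0, 400, 800), n))
  b <- rep(rnorm(n, 0, 2), each = k)
  y <- 100 + b + rnorm(n * k, 0, 1)
  m <- matrix(y, 1, dimnames = list("volume__r", rec$scan_id))
  fit <- fit_feature_lmm(ft_from_matrix(rec, m), "volume__r",
                         ranef = "intercept_only")
  expect_equal(unname(fit$varcomp["subject_intercept"]), 4, tolerance = 0.15)
  expect_equal(fit$sigma_e, 1, tolerance = 0.15)
})

test_that("random slopes are estimated when requested", {
  set.seed(53)
  n <- 60
  k <- 3
  rec <- make_records(rep(paste0("s", 1:n), each = k),
                      paste0("sc", seq_len(n * k)),
                      scanner = rep_len(c(1L, 2L, 2L), n * k),
                      day = rep(c(0, 500, 1000), n))
  b0 <- rep(rnorm(n, 0, 2), each = k)
  b1 <- rep(rnorm(n, 0, 1), each = k)
  t_yr <- rec$days_since_first_scan / 365.25
  y <- 100 + b0 + b1 * t_yr + rnorm(n * k, 0, 0.5)
  m <- matrix(y, 1, dimnames = list("volume__r", rec$scan_id))
  fit <- suppressWarnings(
    fit_feature_lmm(ft_from_matrix(rec, m), "volume__r",
                    ranef = "intercept_slope"))
  expect_true(all(c("subject_intercept", "subject_slope",
                    "intercept_slope_cov") %in% names(fit$varcomp)))
  expect_equal(unname(fit$varcomp["subject_slope"]), 1, tolerance = 0.35)
})

test_that("single scan per subject degenerates to the cross-sectional model", {
  ft <- toy_three_feature()
  out_long <- quiet_longcombat(ft, eb = FALSE, ranef = "intercept_only")
  out_cross <- harmonize_neurocombat(ft, eb = FALSE)
  expect_equal(ft_matrix(out_long), ft_matrix(out_cross), tolerance = 1e-6)
})

test_that("output preserves row count, order and annotations", {
  sim <- simulate_cohort(make_scenario("scanner_effect", seed = 61,
    n_subjects_within = 15, n_subjects_across = 8,
    n_subjects_longitudinal = 8, n_scanners = 3))
  out <- quiet_longcombat(sim$table, std_covariates,
                          ranef = "intercept_only")
  expect_identical(out$records, sim$table$records)
  expect_identical(out$values$scan_id, sim$table$values$scan_id)
  expect_identical(out$values$feature, sim$table$values$feature)
})

test_that("eb = FALSE equalizes per-scanner standardized residual means", {
  sim <- simulate_cohort(make_scenario("scanner_effect", seed = 67,
    n_subjects_within = 20, n_subjects_across = 10,
    n_subjects_longitudinal = 0, n_scanners = 3,
    rois = "r1", baseline_mean = c(r1 = 1000)))
  out <- quiet_longcombat(sim$table, eb = FALSE, ranef = "intercept_only")
  # refit the mixed model on the adjusted values: scanner offsets now ~0
  refit <- suppressWarnings(
    fit_feature_lmm(out, "volume__r1", ranef = "intercept_only"))
  expect_lt(max(abs(refit$gamma_raw)), 0.05 * max(abs(
    suppressWarnings(fit_feature_lmm(sim$table, "volume__r1",
                                     ranef = "intercept_only"))$gamma_raw)))
})

test_that("null scenario preserves within-subject trajectories", {
  sim <- simulate_cohort(make_scenario("no_scanner_effect", seed = 71,
    n_subjects_within = 0, n_subjects_across = 0,
    n_subjects_longitudinal = 30, n_scanners = 3))
  out <- quiet_longcombat(sim$table, std_covariates,
                          ranef = "intercept_only")
  y0 <- ft_matrix(sim$table); y1 <- ft_matrix(out)
  rec <- sim$table$records
  slope_of <- function(m) {
    vapply(unique(rec$subject_id), function(s) {
      idx <- rec$subject_id == s
      stats::coef(stats::lm(m[1, idx] ~ rec$days_since_first_scan[idx]))[2]
    }, numeric(1))
  }
  expect_gt(stats::cor(slope_of(y0), slope_of(y1)), 0.99)
})

test_that("scanner_effect scenario: follow-up discrepancy CoV is reduced", {
  sim <- simulate_cohort(make_scenario("scanner_effect", seed = 73,
    n_subjects_within = 10, n_subjects_across = 5,
    n_subjects_longitudinal = 25, n_scanners = 3))
  coh <- derive_cohorts(sim$table)
  out <- quiet_longcombat(sim$table, std_covariates,
                          ranef = "intercept_only")
  cov0 <- triplet_covs(sim$table, coh)
  cov1 <- triplet_covs(out, coh)
  expect_lt(mean(cov1$cov), mean(cov0$cov))
})
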
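test_that("location-shift model equalizes the toy two-batch instance at 7.0", {
  ft <- toy_two_batch()
  out <- harmonize_neurocombat(ft, covariates = NULL, eb = FALSE)
  m <- ft_matrix(out)
  batch <- ft$records$scanner_id
  means <- tapply(m[1, ], batch, mean)
  expect_equal(as.numeric(means), c(7, 7), tolerance = 1e-10)
  # exact hand-derived values: 7 +/- sqrt(2/3) around each batch mean
  expect_equal(sort(m[1, 1:3]), 7 + sqrt(2 / 3) * (-1:1),
               tolerance = 1e-10, ignore_attr = TRUE)

  mod <- attr(out, "model")
  # weighted sum-to-zero and two-batch symmetry of the additive estimates
  expect_equal(sum(as.numeric(table(batch)) * mod$gamma_hat[, 1]), 0,
               tolerance = 1e-12)
  expect_equal(mod$gamma_hat[1, 1], -mod$gamma_hat[2, 1], tolerance = 1e-12)
  expect_equal(mod$alpha, 7, tolerance = 1e-12)
})

test_that("identical batches yield zero additive effects", {
  rec <- make_records(paste0("s", 1:6), paste0("sc", 1:6),
                      scanner = rep(1:2, each = 3))
  m <- matrix(rep(c(5, 6, 7), 2), nrow = 1,
              dimnames = list("volume__r", rec$scan_id))
  mod <- fit_standardization(ft_from_matrix(rec, m))
  expect_equal(unname(mod$gamma_hat[, 1]), c(0, 0), tolerance = 1e-12)
})

test_that("covariate-only signal is recovered exactly at zero noise", {
  set.seed(5)
  rec <- make_records(paste0("s", 1:20), paste0("sc", 1:20),
                      scanner = rep(1:2, 10), age = runif(20, 20, 80))
  y <- 2 * rec$age_years + 100
  m <- rbind(matrix(y, 1), matrix(0.5 * y, 1))
  dimnames(m) <- list(c("volume__a", "volume__b"), rec$scan_id)
  mod <- fit_standardization(ft_from_matrix(rec, m),
                             covariates = "age_years")
  expect_equal(unname(mod$beta[1, 1]), 2, tolerance = 1e-9)
  expect_equal(unname(mod$beta[1, 2]), 1, tolerance = 1e-9)
  # raw-unit additive offsets vanish (the standardized ones are 0/0 at zero
  # residual noise, so compare before dividing by sigma)
  raw_gamma <- sweep(mod$gamma_hat, 2, mod$sigma, `*`)
  expect_equal(max(abs(raw_gamma)), 0, tolerance = 1e-6)
})

test_that("hyperprior moments follow the method-of-moments formulas", {
  # three features with additive estimates {-1, 0, 1}: mean 0, variance 1
  rec <- make_records(paste0("s", 1:8), paste0("sc", 1:8),
                      scanner = rep(1:2, each = 4))
  set.seed(9)
  base <- matrix(rnorm(3 * 8, sd = 1), 3)
  mod <- list(gamma_hat = rbind(c(-1, 0, 1), c(1, 0, -1)),
              delta_hat_sq = rbind(c(1, 1, 1), c(2, 2, 2)))
  pri <- scancombat:::.eb_hyperpriors(mod$gamma_hat, mod$delta_hat_sq)
  expect_equal(unname(pri$gamma_bar), c(0, 0))
  expect_equal(unname(pri$tau_sq), c(1, 1))
  # degenerate delta spread: inverse-gamma prior mean equals the common value
  expect_equal(unname(pri$theta / (pri$lambda - 1)), c(1, 2),
               tolerance = 1e-6)
})

test_that("parametric shrinkage has the correct limits", {
  ft <- toy_three_feature()
  mod <- fit_standardization(ft)
  mod <- estimate_hyperpriors(mod)

  # tau^2 -> infinity: no shrinkage of gamma
  flat <- mod
  flat$hyperpriors$tau_sq[] <- 1e12
  flat <- eb_shrink(flat)
  expect_equal(flat$gamma_star, mod$gamma_hat, tolerance = 1e-4)

  # tau^2 = 0: total shrinkage to the prior mean
  tight <- mod
  tight$hyperpriors$tau_sq[] <- 0
  tight <- eb_shrink(tight)
  for (b in 1:2) {
    expect_equal(unname(tight$gamma_star[b, ]),
                 rep(unname(mod$hyperpriors$gamma_bar[b]), 3),
                 tolerance = 1e-6)
  }

  # eb = FALSE leaves estimates untouched in the output model
  out <- harmonize_neurocombat(ft, eb = FALSE)
  m <- attr(out, "model")
  expect_null(m$gamma_star)
})

test_that("adjusted values match the brute-force oracle to 1e-10", {
  ft <- toy_three_feature()
  Y <- ft_matrix(ft)
  batch <- ft$records$scanner_id

  out_ls <- harmonize_neurocombat(ft, eb = FALSE)
  expect_equal(ft_matrix(out_ls), oracle_combat(Y, batch, eb = FALSE),
               tolerance = 1e-10)

  out_eb <- harmonize_neurocombat(ft, eb = TRUE, parametric = TRUE)
  expect_equal(ft_matrix(out_eb),
               oracle_combat(Y, batch, eb = TRUE, parametric = TRUE),
               tolerance = 1e-10)
})

test_that("empirical-Bayes shrinkage dominates raw estimates in MSE", {
  set.seed(21)
  V <- 200; n <- 8
  tau <- 0.6
  rec <- make_records(paste0("s", 1:(2 * n)), paste0("sc", 1:(2 * n)),
                      scanner = rep(1:2, each = n))
  g_true <- rbind(rnorm(V, 0, tau), rnorm(V, 0, tau))
  m <- matrix(rnorm(V * 2 * n), V)
  for (b in 1:2) {
    idx <- rec$machine == paste0("scanner", b)
    m[, idx] <- m[, idx] + g_true[b, ]
  }
  m <- m + 100
  dimnames(m) <- list(paste0("volume__f", seq_len(V)), rec$scan_id)
  ft <- ft_from_matrix(rec, m)

  mod <- fit_standardization(ft)
  # express the truth on the model's scale: weighted-sum-to-zero across the
  # two equal batches, divided by the per-feature pooled SD
  truth_std <- sweep(sweep(g_true, 2, colMeans(g_true)), 2, mod$sigma, `/`)
  for (parametric in c(TRUE, FALSE)) {
    sh <- eb_shrink(mod, parametric = parametric)
    mse_raw <- mean((sh$gamma_hat - truth_std)^2)
    mse_star <- mean((sh$gamma_star - truth_std)^2)
    expect_lt(mse_star, mse_raw)
  }
})

test_that("re-standardized residuals are centered and unit-variance after eb = FALSE", {
  sim <- simulate_cohort(make_scenario("scanner_effect", seed = 13,
    n_subjects_within = 20, n_subjects_across = 10,
    n_subjects_longitudinal = 0, n_scanners = 3))
  out <- harmonize_neurocombat(sim$table, eb = FALSE)
  mod <- attr(out, "model")
  # re-standardize the adjusted data with the original model's mean and SD:
  # per batch and feature the residuals are centered with unit (n-1) variance
  z_adj <- (ft_matrix(out) - mod$stand_mean) / mod$sigma
  for (b in levels(mod$batch)) {
    zb <- z_adj[, mod$batch == b, drop = FALSE]
    expect_equal(unname(rowMeans(zb)), rep(0, nrow(zb)), tolerance = 1e-8)
    expect_equal(unname(apply(zb, 1, stats::var)), rep(1, nrow(zb)),
                 tolerance = 1e-8)
  }
})

test_that("equal-n batch swap negates gamma and preserves output", {
  ft <- toy_three_feature()
  out1 <- harmonize_neurocombat(ft, eb = FALSE)
  # relabel the two equal-sized batches
  rec2 <- ft$records
  rec2$machine <- rev(rec2$machine)
  rec2$scanner_id <- NULL
  ft2 <- feature_table(rec2, ft$values, ft$metric)
  out2 <- harmonize_neurocombat(ft2, eb = FALSE)
  expect_equal(ft_matrix(out1), ft_matrix(out2), tolerance = 1e-10)
  g1 <- attr(out1, "model")$gamma_hat
  g2 <- attr(out2, "model")$gamma_hat
  expect_equal(unname(g1[1, ]), unname(-g2[1, ]), tolerance = 1e-10)
})

test_that("large-tau flat-prior parametric EB approaches the location-shift output", {
  set.seed(31)
  n <- 200   # large batches: the n vs n-1 variance divisors then agree closely
  rec <- make_records(paste0("s", 1:(2 * n)), paste0("sc", 1:(2 * n)),
                      scanner = rep(1:2, each = n))
  m <- matrix(100 + rnorm(3 * 2 * n, sd = 4), 3)
  m[, rec$machine == "scanner2"] <- m[, rec$machine == "scanner2"] + c(2, -1, 3)
  dimnames(m) <- list(paste0("volume__f", 1:3), rec$scan_id)
  ft <- ft_from_matrix(rec, m)

  mod <- estimate_hyperpriors(fit_standardization(ft))
  mod$hyperpriors$tau_sq[] <- 1e10
  mod$hyperpriors$lambda[] <- 1 + 1e-10
  mod$hyperpriors$theta[] <- 1e-12
  mod <- eb_shrink(mod, tol = 1e-10)
  adj_eb <- scancombat:::.combat_apply(mod, ft_matrix(ft))
  adj_ls <- ft_matrix(harmonize_neurocombat(ft, eb = FALSE))
  expect_lt(max(abs(adj_eb - adj_ls)) / stats::sd(m), 0.01)
})

test_that("null-scenario harmonization is near the identity", {
  sim <- simulate_cohort(make_scenario("no_scanner_effect", seed = 17,
    n_subjects_within = 30, n_subjects_across = 15,
    n_subjects_longitudinal = 0, n_scanners = 3))
  out <- harmonize_neurocombat(sim$table, std_covariates, eb = FALSE)
  y0 <- ft_matrix(sim$table); y1 <- ft_matrix(out)
  # per-feature change small relative to the model's residual SD (which
  # includes between-subject spread): pure re-estimation jitter
  rel <- abs(y1 - y0) / attr(out, "model")$sigma
  # worst-case scan bounded, typical scan far smaller
  expect_true(all(rel < 1.5))
  expect_lt(mean(rel), 0.25)
})

test_that("scanner_effect scenario: across-batch mean differences shrink > 90%", {
  # 50 features so the empirical-Bayes priors are well estimated; subject
  # and covariate effects are switched off so the across-batch gap isolates
  # the scanner effect rather than cohort-composition differences (which
  # harmonization rightly preserves)
  rois <- sprintf("r%02d", 1:50)
  sim <- simulate_cohort(make_scenario("scanner_effect", seed = 23,
    n_subjects_within = 40, n_subjects_across = 20,
    n_subjects_longitudinal = 0, n_scanners = 2,
    rois = rois, baseline_mean = stats::setNames(rep(1000, 50), rois),
    subject_sd_pct = 0, age_slope_pct = 0, sex_offset_pct = 0,
    icv_slope_pct = 0, annual_change_sd_pct = 0))
  y0 <- ft_matrix(sim$table)
  batch <- sim$table$records$scanner_id
  gap <- function(m) {
    apply(m, 1, function(x) abs(diff(tapply(x, batch, mean))))
  }
  for (eb in c(TRUE, FALSE)) {
    y1 <- ft_matrix(harmonize_neurocombat(sim$table, eb = eb))
    expect_true(all(gap(y1) < 0.1 * gap(y0)))
  }
})

test_that("covariate relationships survive harmonization", {
  sim <- simulate_cohort(make_scenario("scanner_effect", seed = 29,
    n_subjects_within = 40, n_subjects_across = 0,
    n_subjects_longitudinal = 0, n_scanners = 2))
  mod0 <- fit_standardization(sim$table, std_covariates)
  out <- harmonize_neurocombat(sim$table, std_covariates)
  mod1 <- fit_standardization(out, std_covariates)
  # raw-unit covariate slopes: beta is stored per standardized model fit
  expect_equal(mod1$beta, mod0$beta, tolerance = 0.05)
})

test_that("guard rails reject degenerate designs", {
  rec <- make_records(paste0("s", 1:3), paste0("sc", 1:3), scanner = 1L)
  m <- matrix(1:3, 1, dimnames = list("volume__r", rec$scan_id))
  expect_error(harmonize_neurocombat(ft_from_matrix(rec, m)),
               "at least 2 scanners")

  rec2 <- make_records(paste0("s", 1:3), paste0("sc", 1:3),
                       scanner = c(1L, 1L, 2L))
  m2 <- matrix(1:3, 1, dimnames = list("volume__r", rec2$scan_id))
  expect_error(harmonize_neurocombat(ft_from_matrix(rec2, m2)),
               "single scan")

  # collinear covariates are named
  rec3 <- make_records(paste0("s", 1:6), paste0("sc", 1:6),
                       scanner = rep(1:2, each = 3), age = 50)
  m3 <- matrix(1:6 + 10, 1, dimnames = list("volume__r", rec3$scan_id))
  expect_error(
    fit_standardization(ft_from_matrix(rec3, m3), c("age_years")),
    "collinear.*age_years")

  expect_error(estimate_hyperpriors(fit_standardization(toy_two_batch())),
               "eb = FALSE")
})
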
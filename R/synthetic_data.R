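#' Default regions of interest for the volume metric
#' @keywords internal
.default_rois <- c(
  "ventricles", "cortical_GM", "supratentorial_WM", "supratentorial_DGM",
  "cerebellar_GM", "cerebellar_WM", "brainstem"
)

# mm^3, plausible adult means per ROI
.default_baselines <- c(
  ventricles = 25000, cortical_GM = 480000, supratentorial_WM = 440000,
  supratentorial_DGM = 60000, cerebellar_GM = 95000, cerebellar_WM = 25000,
  brainstem = 28000
)

# small-sample bias of the SD of a pair of Gaussians: E[sd(x1,x2)] = c4 * sigma
.c4_pair <- sqrt(2 / pi)

#' Configuration of the travelling-subject cohort simulator
#'
#' Assembles the generative model for a synthetic multi-scanner cohort.
#' Per feature (ROI) v, subject j, scanner i, time t (years since the
#' subject's first scan), a scan value is generated as
#' \deqn{y = (\mu_v (1 + s_{jv} + b^{age}_v (age-50) + b^{sex}_v male +
#'   b^{icv}_v z_{icv} + r_{jv} t) + \gamma_{iv}) \delta_i + \epsilon}
#' with additive scanner offsets \eqn{\gamma_{iv}} applied before the
#' multiplicative scanner factor \eqn{\delta_i}, matching the
#' additive-then-multiplicative structure of the ComBat model. Relative
#' parameters (`*_pct`) are percent of the ROI baseline mean \eqn{\mu_v}.
#' The noise SD is calibrated so that the expected scan-rescan pair
#' coefficient of variation equals `noise_cov_percent` (the SD of a pair of
#' Gaussian draws is biased low by \eqn{\sqrt{2/\pi}}; the calibration
#' divides by that constant).
#'
#' Cohort sizes default to the scale of a travelling-subject validation
#' study: ~50 within-scanner pair subjects, ~28 across-scanner pair
#' subjects, ~16 longitudinal-triplet subjects over 5 scanners.
#'
#' @param n_subjects_within,n_subjects_across,n_subjects_longitudinal
#'   Subjects in the within-scanner pair, across-scanner pair and
#'   longitudinal triplet cohorts.
#' @param n_scanners Number of scanners (>= 2).
#' @param rois Character vector of ROI names (default: 7 volume ROIs).
#' @param metric Feature metric, see [feature_table()].
#' @param age_range Age at first scan, uniform over this range (years).
#' @param male_fraction Probability of male sex.
#' @param baseline_mean Named positive vector, one mean per ROI.
#' @param age_slope_pct,sex_offset_pct,icv_slope_pct Per-ROI covariate
#'   effects: percent of baseline per year of age (centered at 50), percent
#'   offset for male sex, percent per SD of log-ICV.
#' @param annual_change_pct Per-ROI mean true biological rate of change,
#'   percent of baseline per year.
#' @param annual_change_sd_pct Between-subject SD of the true rate,
#'   percent of baseline per year.
#' @param scanner_additive_pct Per-scanner additive offset gamma, percent of
#'   each ROI's baseline.
#' @param scanner_multiplicative Per-scanner positive scale factor delta.
#' @param noise_cov_percent Per-ROI target within-scanner scan-rescan CoV
#'   (percent).
#' @param subject_sd_pct Between-subject SD of the stable subject effect,
#'   percent of baseline.
#' @param seed Master seed; every subject draws from an independent stream
#'   derived from it, so adding subjects never perturbs existing ones.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects_within = 50,
                              n_subjects_across = 28,
                              n_subjects_longitudinal = 16,
                              n_scanners = 5,
                              rois = .default_rois,
                              metric = "volume",
                              age_range = c(19, 84),
                              male_fraction = 0.5,
                              baseline_mean = NULL,
                              age_slope_pct = NULL,
                              sex_offset_pct = NULL,
                              icv_slope_pct = NULL,
                              annual_change_pct = NULL,
                              annual_change_sd_pct = 0.5,
                              scanner_additive_pct = rep(0, n_scanners),
                              scanner_multiplicative = rep(1, n_scanners),
                              noise_cov_percent = NULL,
                              subject_sd_pct = 8,
                              seed = 1L) {
  nr <- length(rois)
  if (is.null(baseline_mean)) {
    baseline_mean <- if (identical(rois, .default_rois)) .default_baselines
                     else stats::setNames(rep(1000, nr), rois)
  }
  defvec <- function(x, default) {
    if (is.null(x)) x <- default
    if (length(x) == 1L) x <- rep(x, nr)
    stats::setNames(as.numeric(x), rois)
  }
  cfg <- list(
    n_subjects_within = n_subjects_within,
    n_subjects_across = n_subjects_across,
    n_subjects_longitudinal = n_subjects_longitudinal,
    n_scanners = as.integer(n_scanners),
    rois = rois,
    metric = match.arg(metric, .metrics),
    age_range = age_range,
    male_fraction = male_fraction,
    baseline_mean = stats::setNames(as.numeric(baseline_mean[rois]), rois),
    age_slope_pct = defvec(age_slope_pct,
      rep_len(c(0.8, -0.25, -0.2, -0.2, -0.2, -0.15, -0.1), nr)),
    sex_offset_pct = defvec(sex_offset_pct, 2),
    icv_slope_pct = defvec(icv_slope_pct, 0.8),
    annual_change_pct = defvec(annual_change_pct,
      rep_len(c(1.5, -0.4, -0.3, -0.3, -0.25, -0.2, -0.15), nr)),
    annual_change_sd_pct = annual_change_sd_pct,
    scanner_additive_pct = as.numeric(scanner_additive_pct),
    scanner_multiplicative = as.numeric(scanner_multiplicative),
    noise_cov_percent = defvec(noise_cov_percent,
      rep_len(c(1.6, 0.9, 1.1, 1.4, 2.2, 3.4, 1.2), nr)),
    subject_sd_pct = subject_sd_pct,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_scanners < 2L) stop("n_scanners must be >= 2", call. = FALSE)
  if (length(cfg$scanner_additive_pct) != cfg$n_scanners ||
      length(cfg$scanner_multiplicative) != cfg$n_scanners) {
    stop("scanner effect vectors must have length n_scanners", call. = FALSE)
  }
  if (any(cfg$scanner_multiplicative <= 0)) {
    stop("scanner_multiplicative must be > 0", call. = FALSE)
  }
  if (any(cfg$noise_cov_percent < 0)) {
    stop("noise_cov_percent must be >= 0", call. = FALSE)
  }
  if (any(cfg$baseline_mean <= 0)) {
    stop("baseline_mean must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Packaged simulation scenarios
#'
#' Two stock configurations mirroring the two situations seen in
#' travelling-subject studies: structural-like data with no scanner effect
#' (all gamma = 0, delta = 1) and diffusion-like data with marked additive
#' and multiplicative scanner effects on top of within-scanner noise in the
#' ~1-3.5% CoV range.
#'
#' Both scenarios share all demographic and schedule parameters, so two
#' simulations with the same seed differ only in scanner effects and noise
#' realization scaling.
#'
#' @param name `"no_scanner_effect"` or `"scanner_effect"`.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
make_scenario <- function(name = c("no_scanner_effect", "scanner_effect"),
                          ...) {
  name <- match.arg(name)
  dots <- list(...)
  n_scanners <- if (!is.null(dots$n_scanners)) dots$n_scanners else 5L
  eff <- switch(name,
    no_scanner_effect = list(
      scanner_additive_pct = rep(0, n_scanners),
      scanner_multiplicative = rep(1, n_scanners)),
    scanner_effect = list(
      scanner_additive_pct =
        c(0, 3, -2.5, 4, -3, 2, -2)[seq_len(n_scanners)],
      scanner_multiplicative =
        c(1, 1.06, 0.95, 1.05, 0.93, 1.04, 0.96)[seq_len(n_scanners)])
  )
  args <- utils::modifyList(c(eff, list(n_scanners = n_scanners)), dots)
  do.call(simulation_config, args)
}

# independent, reproducible stream per subject: mix master seed and index
.subject_seed <- function(seed, k) {
  s <- (as.double(seed) * 2654435761 + as.double(k) * 40503) %% 2147483629
  as.integer(s) + 1L
}

#' Simulate a travelling-subject cohort with known ground truth
#'
#' Generates a [feature_table()] containing the three validation cohorts:
#' within-scanner scan pairs (interval < 180 days), across-scanner scan
#' pairs (interval < 180 days) and longitudinal triplets (reference scan
#' plus a same-scanner and a different-scanner follow-up > 365 days later,
#' within ~6 months of each other). Scanners are allocated round-robin over
#' subjects so every scanner is populated.
#'
#' @param config A [simulation_config()].
#' @return A list with elements
#'   * `table`: the generated `feature_table`;
#'   * `truth`: ground truth — `gamma` (scanner x ROI additive offsets,
#'     feature units), `delta` (per-scanner scale factors), `noise_sd`
#'     (per-ROI scan noise SD), `subject_effects` and `subject_rates`
#'     (subject x ROI, feature units and units/year), `betas`, the
#'     baseline means, and the config. Sufficient to reconstruct expected
#'     values exactly when the noise SD is zero.
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_simulation_config(config)
  nr <- length(cfg$rois)
  ns <- cfg$n_scanners
  baseline <- cfg$baseline_mean
  noise_sd <- baseline * cfg$noise_cov_percent / 100 / .c4_pair
  gamma <- outer(cfg$scanner_additive_pct / 100, baseline) # scanner x roi
  rownames(gamma) <- paste0("scanner", seq_len(ns))
  delta <- cfg$scanner_multiplicative

  # negative-value guard: per ROI, approximate lower tail at the least
  # favourable scanner and a 3-sigma subject effect
  mu_mat <- outer(delta, baseline * (1 - 3 * cfg$subject_sd_pct / 100)) +
    sweep(gamma, 1, delta, `*`)                      # scanner x roi
  mu_min <- apply(mu_mat, 2, min)
  if (any(stats::pnorm(0, mu_min, noise_sd) > 0.001)) {
    warning("configuration implies negative feature values with probability > 0.1%")
  }

  subjects <- c(
    if (cfg$n_subjects_within > 0)
      sprintf("W%03d", seq_len(cfg$n_subjects_within)),
    if (cfg$n_subjects_across > 0)
      sprintf("A%03d", seq_len(cfg$n_subjects_across)),
    if (cfg$n_subjects_longitudinal > 0)
      sprintf("L%03d", seq_len(cfg$n_subjects_longitudinal))
  )
  cohort_of <- substr(subjects, 1, 1)

  rec_list <- list()
  val_list <- list()
  subj_eff <- matrix(NA_real_, length(subjects), nr,
                     dimnames = list(subjects, cfg$rois))
  subj_rate <- subj_eff

  for (k in seq_along(subjects)) {
    sub <- subjects[k]
    set.seed(.subject_seed(cfg$seed, k))
    male <- stats::rbinom(1, 1, cfg$male_fraction)
    age0 <- stats::runif(1, cfg$age_range[1], cfg$age_range[2])
    z_icv <- stats::rnorm(1)
    icv <- exp(log(1.5e6) + 0.05 * male + 0.08 * z_icv)
    s_jv <- stats::rnorm(nr, 0, cfg$subject_sd_pct / 100)
    r_jv <- cfg$annual_change_pct / 100 +
      stats::rnorm(nr, 0, cfg$annual_change_sd_pct / 100)
    subj_eff[k, ] <- s_jv * baseline
    subj_rate[k, ] <- r_jv * baseline

    base_scanner <- 1L + (k - 1L) %% ns
    other <- 1L + k %% ns
    if (other == base_scanner) other <- 1L + (k + 1L) %% ns

    sched <- switch(cohort_of[k],
      W = { # two scans, same scanner, < 180 days apart
        gap <- sample(2:170, 1)
        data.frame(day = c(0L, gap), scanner = c(base_scanner, base_scanner))
      },
      A = { # two scans, different scanners, < 180 days apart
        gap <- sample(2:170, 1)
        data.frame(day = c(0L, gap), scanner = c(base_scanner, other))
      },
      L = { # reference + same-scanner and different-scanner follow-ups
        t_w <- sample(500:1800, 1)
        t_a <- max(t_w + sample(-150:150, 1), 400L)
        data.frame(day = c(0L, t_w, t_a),
                   scanner = c(base_scanner, base_scanner, other))
      })

    n_scan <- nrow(sched)
    eps <- matrix(stats::rnorm(n_scan * nr), n_scan, nr)
    for (s in seq_len(n_scan)) {
      t_yr <- sched$day[s] / 365.25
      i <- sched$scanner[s]
      mu <- baseline * (1 + s_jv +
                          cfg$age_slope_pct / 100 * (age0 + t_yr - 50) +
                          cfg$sex_offset_pct / 100 * male +
                          cfg$icv_slope_pct / 100 * z_icv +
                          r_jv * t_yr)
      y <- (mu + gamma[i, ]) * delta[i] + eps[s, ] * noise_sd
      scan_id <- sprintf("%s_s%d", sub, s)
      rec_list[[length(rec_list) + 1L]] <- data.frame(
        subject_id = sub, scan_id = scan_id,
        site = ifelse(i %% 2 == 0, "siteB", "siteA"),
        machine = paste0("scanner", i),
        protocol = paste0("prot", i),
        days_since_first_scan = sched$day[s],
        age_years = age0 + t_yr, sex = ifelse(male == 1, "M", "F"),
        icv = icv, stringsAsFactors = FALSE)
      val_list[[length(val_list) + 1L]] <- data.frame(
        scan_id = scan_id,
        feature = paste0(cfg$metric, "__", cfg$rois),
        value = as.numeric(y), stringsAsFactors = FALSE)
    }
  }

  records <- do.call(rbind, rec_list)
  values <- do.call(rbind, val_list)
  feats <- paste0(cfg$metric, "__", cfg$rois)
  colnames(gamma) <- feats
  colnames(subj_eff) <- colnames(subj_rate) <- feats

  list(
    table = feature_table(records, values, cfg$metric),
    truth = list(
      gamma = gamma,
      delta = delta,
      noise_sd = stats::setNames(noise_sd, feats),
      subject_effects = subj_eff,
      subject_rates = subj_rate,
      betas = list(age_slope = baseline * cfg$age_slope_pct / 100,
                   sex_offset = baseline * cfg$sex_offset_pct / 100,
                   icv_slope = baseline * cfg$icv_slope_pct / 100),
      baseline_mean = baseline,
      config = cfg
    )
  )
}
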
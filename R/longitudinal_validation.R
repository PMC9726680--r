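#' @title Longitudinal scanner-effect quantification and agreement
#' @description
#' Tools for the longitudinal travelling-subject design: annualized rates
#' of change, the follow-up interval adjustment that puts the
#' across-scanner follow-up on the within-scanner follow-up's date,
#' per-subject scanner-effect CoVs, a mixed-model comparison of
#' harmonization methods, and intra-class correlation agreement between
#' across-scanner observed rates and the same-scanner ground truth.
#' @name longitudinal_validation
NULL

#' Annual rate of change between two scans
#'
#' @param v1,v2 Feature values at the earlier and later scan.
#' @param dt_years Positive interval in years.
#' @return `(v2 - v1) / dt_years`, in feature units per year.
#' @export
annual_rate <- function(v1, v2, dt_years) {
  if (any(dt_years <= 0)) stop("dt_years must be positive", call. = FALSE)
  (v2 - v1) / dt_years
}

#' Interval-adjust the across-scanner follow-up value
#'
#' Computes what the across-scanner follow-up measurement would have been
#' had that scan been acquired on the same day as the within-scanner
#' follow-up:
#' \deqn{value_{adjusted} = value_{reference} + time_{within} \cdot
#'       rate_{across}}
#' where `rate_across` is the annualized change between the reference scan
#' and the across-scanner follow-up. When the two follow-up intervals are
#' equal this reproduces the across-scanner value exactly; with a zero rate
#' it returns the reference value.
#'
#' @param value_reference Feature value at the reference scan.
#' @param rate_across Annualized rate of change to the across-scanner
#'   follow-up (units/year).
#' @param time_within Interval from reference to the within-scanner
#'   follow-up (years, positive).
#' @return The interval-adjusted across-scanner follow-up value.
#' @export
#' @examples
#' adjust_across_value(100, -2, 5)  # 90
adjust_across_value <- function(value_reference, rate_across, time_within) {
  if (any(time_within <= 0)) stop("time_within must be positive",
                                  call. = FALSE)
  value_reference + time_within * rate_across
}

#' Per-subject scanner-effect CoV of a longitudinal triplet
#'
#' The pair CoV of the within-scanner follow-up value and the
#' interval-adjusted across-scanner follow-up value; the discrepancy
#' between the two is attributed to the scanner.
#'
#' @param value_within Within-scanner follow-up value.
#' @param value_adjusted Adjusted across-scanner follow-up value
#'   (see [adjust_across_value()]).
#' @return CoV in percent.
#' @export
triplet_scanner_cov <- function(value_within, value_adjusted) {
  pair_cov(value_within, value_adjusted)
}

#' Triplet-level rates and scanner-effect CoVs for one dataset
#'
#' For every longitudinal triplet and feature: annualized rates of change
#' to both follow-ups, the adjusted across-scanner value and the
#' scanner-effect CoV.
#'
#' @param ft A `feature_table`.
#' @param cohorts A [derive_cohorts()] result with non-empty
#'   `longitudinal_triplets`.
#' @return Data frame with one row per (triplet, feature): `subject`,
#'   `feature`, `rate_within`, `rate_across`, `value_within`,
#'   `value_adjusted`, `cov`.
#' @export
triplet_covs <- function(ft, cohorts) {
  trips <- cohorts$longitudinal_triplets
  if (nrow(trips) == 0L) {
    stop("empty cohort: longitudinal_triplets", call. = FALSE)
  }
  m <- ft_matrix(ft)
  day <- stats::setNames(ft$records$days_since_first_scan,
                         ft$records$scan_id)
  sub <- stats::setNames(ft$records$subject_id, ft$records$scan_id)
  out <- list()
  for (i in seq_len(nrow(trips))) {
    ref <- trips$reference[i]
    fw <- trips$within_followup[i]
    fa <- trips$across_followup[i]
    t_w <- (day[fw] - day[ref]) / 365.25
    t_a <- (day[fa] - day[ref]) / 365.25
    r_w <- annual_rate(m[, ref], m[, fw], t_w)
    r_a <- annual_rate(m[, ref], m[, fa], t_a)
    v_adj <- adjust_across_value(m[, ref], r_a, t_w)
    out[[i]] <- data.frame(
      subject = unname(sub[ref]), feature = rownames(m),
      time_within = unname(t_w), time_across = unname(t_a),
      rate_within = unname(r_w), rate_across = unname(r_a),
      value_within = unname(m[, fw]), value_adjusted = unname(v_adj),
      cov = unname(triplet_scanner_cov(m[, fw], v_adj)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mixed-model comparison of harmonization methods on triplet CoVs
#'
#' REML fit of `cov ~ method + (1 | subject)` with the unharmonized data as
#' the reference level. A method's coefficient is its change in
#' scanner-effect CoV (percentage points) relative to unharmonized data;
#' the method is flagged significant when the 95% Wald confidence interval
#' excludes 0. No multiplicity correction is applied across methods.
#'
#' @param cov_table Data frame with columns `subject`, `method`, `cov`
#'   (additional columns such as `feature` are allowed and treated as
#'   repeated measures within subject). Must contain the level
#'   `"unharmonized"` and at least one other method.
#' @return Data frame: `method`, `estimate`, `se`, `ci_lower`, `ci_upper`,
#'   `significant`.
#' @export
method_effect_lmm <- function(cov_table) {
  stopifnot(all(c("subject", "method", "cov") %in% names(cov_table)))
  meths <- unique(cov_table$method)
  if (length(meths) < 2L) {
    stop("need at least 2 methods including the unharmonized baseline",
         call. = FALSE)
  }
  if (!"unharmonized" %in% meths) {
    stop("cov_table must contain the 'unharmonized' baseline", call. = FALSE)
  }
  cov_table$method <- stats::relevel(factor(cov_table$method),
                                     ref = "unharmonized")
  fit <- withCallingHandlers(
    lme4::lmer(cov ~ method + (1 | subject), data = cov_table, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    message = function(m) invokeRestart("muffleMessage"))
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  keep <- grep("^method", names(cf))
  est <- cf[keep]
  se <- se[keep]
  data.frame(
    method = sub("^method", "", names(est)),
    estimate = unname(est), se = unname(se),
    ci_lower = unname(est - 1.96 * se),
    ci_upper = unname(est + 1.96 * se),
    significant = unname(abs(est) - 1.96 * se > 0),
    stringsAsFactors = FALSE)
}

#' Two-way random-effects absolute-agreement ICC, single measurement
#'
#' ICC(A,1) from the two-way ANOVA mean squares of the subjects x raters
#' table:
#' \deqn{ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E +
#'       k (MS_C - MS_E)/n).}
#' Absolute agreement (not consistency): a constant offset between the two
#' columns lowers the coefficient, as required when a value of 1 must mean
#' the entire biological effect is recovered.
#'
#' @param x,y Paired measurements (equal length >= 3), e.g. across-scanner
#'   observed and same-scanner ground-truth annualized rates.
#' @return ICC(A,1) in \[-1, 1\].
#' @export
icc_a1 <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("ICC needs at least 3 paired values", call. = FALSE)
  vals <- c(x, y)
  if (stats::var(vals) == 0) stop("zero total variance: ICC undefined",
                                  call. = FALSE)
  subj <- factor(rep(seq_len(n), 2L))
  rater <- factor(rep(1:2, each = n))
  # only the mean squares are used; the F-test "perfect fit" warning on
  # degenerate inputs is irrelevant here
  av <- suppressWarnings(stats::anova(stats::aov(vals ~ subj + rater)))
  msr <- av["subj", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Agreement of across-scanner rates with the same-scanner ground truth
#'
#' Per dataset and feature, the ICC(A,1) between the annualized rate of
#' change observed via the across-scanner follow-up (harmonization applied
#' to that dataset) and the ground-truth rate measured by rescanning on the
#' reference scanner (taken from the unharmonized data, where no scanner
#' effect contaminates the same-scanner pair). Agreement above 0.5 is
#' labelled `"good"`, otherwise `"poor"`.
#'
#' @param tables Named list of `feature_table`s including `"unharmonized"`.
#' @param cohorts A [derive_cohorts()] result with longitudinal triplets.
#' @return Data frame: `dataset`, `feature`, `icc`, `label`.
#' @export
icc_agreement <- function(tables, cohorts) {
  stopifnot("unharmonized" %in% names(tables))
  truth <- triplet_covs(tables$unharmonized, cohorts)
  out <- list()
  for (ds in names(tables)) {
    obs <- triplet_covs(tables[[ds]], cohorts)
    for (f in unique(obs$feature)) {
      o <- obs[obs$feature == f, ]
      g <- truth[truth$feature == f, ]
      stopifnot(identical(o$subject, g$subject))
      icc <- icc_a1(o$rate_across, g$rate_within)
      out[[length(out) + 1L]] <- data.frame(
        dataset = ds, feature = f, icc = icc,
        label = if (icc > 0.5) "good" else "poor",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
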
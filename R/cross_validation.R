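#' @title Cross-sectional scanner-effect quantification
#' @description
#' Scan-rescan variability statistics for travelling-subject designs: the
#' per-pair coefficient of variation, Welch comparison of across- vs
#' within-scanner CoV distributions, Cohen's d effect sizes with the
#' conventional 0.2/0.5/0.8 labels, and Holm multiplicity adjustment —
#' assembled into a per-ROI scanner-effect report.
#' @name cross_validation
NULL

#' Coefficient of variation of a scan pair, in percent
#'
#' Sample SD (divisor n-1) of the two values divided by their mean, times
#' 100. Symmetric in its arguments and invariant to positive rescaling.
#' Vectorized over pairs.
#'
#' @param a,b Feature values of the two scans.
#' @return CoV in percent.
#' @export
#' @examples
#' pair_cov(90, 110)   # sd = sqrt(200), mean = 100 -> 14.14214
pair_cov <- function(a, b) {
  m <- (a + b) / 2
  if (any(m <= 0)) stop("pair CoV undefined: non-positive pair mean",
                        call. = FALSE)
  s <- abs(a - b) / sqrt(2)     # sample SD of two values
  100 * s / m
}

#' Welch test comparing across- vs within-scanner CoV distributions
#'
#' Two-sample two-sided t-test with the Welch unequal-variance correction
#' (the two cohorts contain different subjects, so equal variances are not
#' guaranteed). A `student = TRUE` flag switches to the pooled-variance
#' Student test.
#'
#' @param within_covs,across_covs Numeric vectors of subject-level CoVs
#'   (length >= 2 each).
#' @param student Use the pooled-variance Student t-test instead of Welch.
#' @return List with elements `t` and `p` (two-sided).
#' @export
scanner_effect_test <- function(within_covs, across_covs, student = FALSE) {
  if (length(within_covs) < 2L || length(across_covs) < 2L) {
    stop("need at least 2 CoVs per cohort", call. = FALSE)
  }
  if (stats::var(within_covs) == 0 && stats::var(across_covs) == 0) {
    # degenerate: both cohorts constant
    if (mean(within_covs) == mean(across_covs)) {
      return(list(t = 0, p = 1))
    }
    return(list(t = Inf * sign(mean(across_covs) - mean(within_covs)), p = 0))
  }
  ht <- stats::t.test(across_covs, within_covs, var.equal = student)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Cohen's d standardized mean difference
#'
#' `(mean(group2) - mean(group1)) / s_pooled` with the pooled SD weighted
#' by n-1 per group. In scanner-effect reports group1 is the
#' within-scanner cohort and group2 the across-scanner cohort, so positive
#' d means the scanner adds variability.
#'
#' @param group1,group2 Numeric vectors (length >= 2 each).
#' @return Cohen's d.
#' @export
cohens_d <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per group",
                               call. = FALSE)
  sp <- sqrt(((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled SD: Cohen's d undefined", call. = FALSE)
  (mean(group2) - mean(group1)) / sp
}

#' Effect-size label for a scanner-effect comparison
#'
#' `"ns"` whenever the Holm-adjusted p-value is >= 0.05; otherwise
#' `"small"`, `"medium"` or `"large"` by |d| thresholds 0.2, 0.5, 0.8.
#' Significant effects with |d| below 0.2 are labelled `"small"`.
#'
#' @param d Cohen's d.
#' @param adj_p Holm-adjusted p-value.
#' @return One of `"ns"`, `"small"`, `"medium"`, `"large"`.
#' @export
effect_label <- function(d, adj_p) {
  if (is.na(adj_p) || adj_p >= 0.05) return("ns")
  if (is.na(d)) return(NA_character_)
  ad <- abs(d)
  if (ad >= 0.8) "large" else if (ad >= 0.5) "medium" else "small"
}

#' Holm step-down multiple-comparison adjustment
#'
#' Step-down adjustment with monotonicity enforcement, order-preserving
#' against input positions (wraps [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "holm")
}

# subject-level pair CoVs for one ROI feature over a pair cohort
.pair_covs <- function(ft, pairs, feature) {
  m <- ft_matrix(ft)
  pair_cov(m[feature, pairs$scan1], m[feature, pairs$scan2])
}

#' Build the per-ROI scanner-effect report
#'
#' For every dataset (unharmonized plus each harmonized version) and every
#' feature: the across-scanner pair CoVs of that dataset are compared with
#' the within-scanner pair CoVs of the unharmonized data (the
#' within-scanner cohort measures random noise not amenable to
#' harmonization and serves as the common reference). Holm adjustment is
#' applied within each dataset column across features. A scanner effect is
#' deemed significant when the adjusted p-value is below 0.05, in which
#' case its magnitude is labelled by Cohen's d thresholds 0.2/0.5/0.8.
#'
#' @param tables Named list of `feature_table`s sharing scans; must include
#'   the element `"unharmonized"`.
#' @param cohorts A [derive_cohorts()] result with non-empty within- and
#'   across-scanner pair cohorts.
#' @param student Use the Student instead of the Welch t-test.
#' @return Data frame of class `scanner_effect_report`: one row per
#'   (dataset, feature) with CoV summaries, `delta_cov`, test statistics,
#'   Holm-adjusted p-values, Cohen's d and the effect label.
#' @export
build_scanner_effect_report <- function(tables, cohorts, student = FALSE) {
  stopifnot(is.list(tables), "unharmonized" %in% names(tables))
  if (nrow(cohorts$within_pairs) == 0L) {
    stop("empty cohort: within_pairs", call. = FALSE)
  }
  if (nrow(cohorts$across_pairs) == 0L) {
    stop("empty cohort: across_pairs", call. = FALSE)
  }
  feats <- ft_features(tables$unharmonized)

  rows <- list()
  for (ds in names(tables)) {
    ds_rows <- lapply(feats, function(f) {
      wc <- .pair_covs(tables$unharmonized, cohorts$within_pairs, f)
      ac <- .pair_covs(tables[[ds]], cohorts$across_pairs, f)
      ht <- scanner_effect_test(wc, ac, student = student)
      data.frame(
        dataset = ds, feature = f,
        within_cov_mean = mean(wc), within_cov_sd = stats::sd(wc),
        across_cov_mean = mean(ac), across_cov_sd = stats::sd(ac),
        delta_cov = mean(ac) - mean(wc),
        t = ht$t, raw_p = ht$p,
        cohens_d = tryCatch(cohens_d(wc, ac), error = function(e) NA_real_),
        stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, ds_rows)
    block$adj_p <- holm_adjust(block$raw_p)
    block$effect_label <- mapply(effect_label, block$cohens_d, block$adj_p)
    rows[[ds]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scanner_effect_report", class(out))
  out
}
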
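#' @title False-positive-rate simulation under random group assignment
#' @description
#' Repeatedly assigns subjects at random to two groups, tests for group
#' differences in intercept and slope with subject-level mixed models, and
#' aggregates the share of nominally significant results per dataset and
#' feature. Since group labels carry no information, any excess over the
#' nominal level is a false-positive inflation introduced by the data or
#' its processing. Friedman and one-sided Wilcoxon tests compare methods
#' and check each method against the accepted 5% threshold.
#' @name fpr_simulation
NULL

#' Randomly assign subjects to groups A and B
#'
#' Independent fair-coin labels per subject (not balanced by construction),
#' reproducible from the seed. All scans of a subject inherit its label.
#'
#' @param subjects Character vector of distinct subject ids (length >= 2).
#' @param seed Integer seed.
#' @return Named character vector of `"A"`/`"B"` labels, one per subject.
#' @export
assign_groups <- function(subjects, seed) {
  if (length(subjects) < 2L) stop("need at least 2 subjects", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  stats::setNames(c("A", "B")[stats::rbinom(length(subjects), 1, 0.5) + 1L],
                  subjects)
}

# Wald p-value for a fixed-effect term of an lmer fit
.wald_p <- function(fit, term) {
  ct <- stats::coef(summary(fit))
  if (!term %in% rownames(ct)) return(NA_real_)
  2 * stats::pnorm(-abs(ct[term, "t value"]))
}

.fpr_ctrl <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    check.conv.singular = "ignore")
}

# fit both group-difference models on a prebuilt frame; NA on failed fit
.group_tests_frame <- function(df, tests) {
  out <- c(intercept = NA_real_, slope = NA_real_)
  if ("intercept" %in% tests) {
    out["intercept"] <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(value ~ group + age_years + sexM + (1 | subject),
                   df, REML = TRUE, control = .fpr_ctrl())))
      .wald_p(fit, "groupB")
    }, error = function(e) NA_real_)
  }
  if ("slope" %in% tests) {
    out["slope"] <- tryCatch({
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(value ~ group * time_years + age_years + sexM +
                     (1 | subject), df, REML = TRUE, control = .fpr_ctrl())))
      .wald_p(fit, "groupB:time_years")
    }, error = function(e) NA_real_)
  }
  out[tests]
}

#' Mixed-model tests for group differences in one feature
#'
#' Intercept test: Wald p-value for the group term in
#' `value ~ group + age + sex + (1 | subject)`. Slope test: Wald p-value
#' for the group x time interaction in
#' `value ~ group * time + age + sex + (1 | subject)`. Both are REML fits;
#' time is years since the subject's first scan.
#'
#' @param ft A `feature_table`.
#' @param labels Named `"A"`/`"B"` vector as from [assign_groups()],
#'   covering every subject; must contain both levels.
#' @param feature Feature name.
#' @param tests Subset of `c("intercept", "slope")`.
#' @return Named numeric vector of unadjusted p-values (NA for a failed
#'   fit).
#' @export
group_difference_tests <- function(ft, labels, feature,
                                   tests = c("intercept", "slope")) {
  tests <- match.arg(tests, several.ok = TRUE)
  grp <- labels[ft$records$subject_id]
  if (length(unique(grp)) < 2L) {
    stop("degenerate contrast: all subjects in one group", call. = FALSE)
  }
  Y <- ft_matrix(ft)
  df <- data.frame(
    value = Y[feature, ],
    group = factor(grp, levels = c("A", "B")),
    age_years = ft$records$age_years,
    sexM = as.numeric(ft$records$sex == "M"),
    time_years = ft$records$days_since_first_scan / 365.25,
    subject = factor(ft$records$subject_id))
  .group_tests_frame(df, tests)
}

#' Estimate false positive rates by repeated random group assignment
#'
#' For each replicate, subjects are relabelled with [assign_groups()]
#' (replicate seeds are `seed + replicate`, so every dataset sees the
#' identical label sequence and comparisons are paired), group-difference
#' models are fitted per dataset and feature, and unadjusted p-values below
#' `alpha` are counted as false positives. Failed fits are excluded from
#' the denominator and reported. When `harmonizers` is supplied,
#' harmonization is re-run within each replicate on the group-labelled
#' table (so `group` can be a harmonization covariate); otherwise the
#' prepared datasets are reused across replicates (static harmonization,
#' recorded in the result's `mode`).
#'
#' @param datasets Named list of `feature_table`s sharing subjects and scan
#'   structure; typically `unharmonized` plus harmonized versions.
#' @param features Features to test (default: all).
#' @param n_reps Number of random assignments (default 1000; fewer than 50
#'   gives an unstable estimate and triggers a warning).
#' @param alpha Nominal significance level (default 0.05).
#' @param seed Integer seed for the replicate label streams.
#' @param tests Subset of `c("intercept", "slope")`.
#' @param harmonizers Optional named list of functions `f(ft) -> ft`
#'   applied to the group-labelled `datasets$unharmonized` within each
#'   replicate (replaces the static datasets of the same name).
#' @return List of class `fpr_result`: `counts` (per dataset, feature,
#'   test: `n_reps`, `n_failed`, `n_positive`, `fpr` in percent),
#'   `median_fpr` (per dataset and test, median across features), `alpha`,
#'   `seed`, `mode`.
#' @export
simulate_fpr <- function(datasets, features = NULL, n_reps = 1000,
                         alpha = 0.05, seed = 1L,
                         tests = c("intercept", "slope"),
                         harmonizers = NULL) {
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  if (n_reps < 50) warning("n_reps < 50 gives an unstable FPR estimate")
  if (!is.null(harmonizers) && !"unharmonized" %in% names(datasets)) {
    stop("per-replicate harmonization needs datasets$unharmonized",
         call. = FALSE)
  }
  base_ft <- datasets[[1L]]
  subjects <- unique(base_ft$records$subject_id)
  if (is.null(features)) features <- ft_features(base_ft)

  ds_names <- union(names(datasets), names(harmonizers))
  # prebuild model frames for the static path
  frames <- lapply(datasets, function(ft) {
    Y <- ft_matrix(ft)
    anno <- data.frame(
      age_years = ft$records$age_years,
      sexM = as.numeric(ft$records$sex == "M"),
      time_years = ft$records$days_since_first_scan / 365.25,
      subject = factor(ft$records$subject_id),
      subject_id = ft$records$subject_id)
    list(Y = Y, anno = anno)
  })

  npos <- nfail <- array(
    0L, dim = c(length(ds_names), length(features), length(tests)),
    dimnames = list(ds_names, features, tests))

  for (r in seq_len(n_reps)) {
    labels <- assign_groups(subjects, seed + r)
    if (length(unique(labels)) < 2L) {
      nfail <- nfail + 1L  # degenerate assignment fails every cell
      next
    }
    rep_frames <- frames
    if (!is.null(harmonizers)) {
      ft_g <- datasets$unharmonized
      ft_g$records$group <- unname(labels[ft_g$records$subject_id])
      for (h in names(harmonizers)) {
        ft_h <- harmonizers[[h]](ft_g)
        rep_frames[[h]] <- list(Y = ft_matrix(ft_h),
                                anno = frames$unharmonized$anno)
      }
    }
    for (ds in ds_names) {
      fr <- rep_frames[[ds]]
      grp <- factor(unname(labels[fr$anno$subject_id]), levels = c("A", "B"))
      df0 <- fr$anno
      df0$group <- grp
      for (f in features) {
        df0$value <- fr$Y[f, ]
        p <- .group_tests_frame(df0, tests)
        for (tt in tests) {
          if (is.na(p[tt])) {
            nfail[ds, f, tt] <- nfail[ds, f, tt] + 1L
          } else if (p[tt] < alpha) {
            npos[ds, f, tt] <- npos[ds, f, tt] + 1L
          }
        }
      }
    }
  }

  counts <- expand.grid(dataset = ds_names, feature = features, test = tests,
                        stringsAsFactors = FALSE)
  counts$n_reps <- n_reps - nfail[cbind(counts$dataset, counts$feature,
                                        counts$test)]
  counts$n_failed <- nfail[cbind(counts$dataset, counts$feature, counts$test)]
  counts$n_positive <- npos[cbind(counts$dataset, counts$feature, counts$test)]
  counts$fpr <- 100 * counts$n_positive / counts$n_reps

  med <- stats::aggregate(fpr ~ dataset + test, counts, stats::median)
  names(med)[names(med) == "fpr"] <- "median_fpr"

  structure(list(counts = counts, median_fpr = med, alpha = alpha,
                 seed = seed,
                 mode = if (is.null(harmonizers)) "static" else "per_replicate"),
            class = "fpr_result")
}

#' @export
print.fpr_result <- function(x, ...) {
  cat(sprintf("<fpr_result> %s harmonization, alpha = %g\n", x$mode, x$alpha))
  print(x$median_fpr)
  invisible(x)
}

#' Friedman comparison of false positive rates across methods
#'
#' Friedman rank test of the features x methods FPR matrix, blocking on
#' feature — the non-parametric analogue of a repeated-measures ANOVA.
#' Multiplicity adjustment across panels is the caller's responsibility.
#'
#' @param fpr_matrix Numeric matrix, rows = features (blocks), columns =
#'   methods (>= 2 of each).
#' @return List with `statistic` (chi-squared), `df` and `p`.
#' @export
friedman_compare <- function(fpr_matrix) {
  fpr_matrix <- as.matrix(fpr_matrix)
  if (ncol(fpr_matrix) < 2L) stop("need at least 2 methods", call. = FALSE)
  if (nrow(fpr_matrix) < 2L) stop("need at least 2 features", call. = FALSE)
  if (all(apply(fpr_matrix, 1, stats::var) == 0)) {
    # every block fully tied: no evidence of any method difference
    return(list(statistic = 0, df = ncol(fpr_matrix) - 1L, p = 1))
  }
  ht <- stats::friedman.test(fpr_matrix)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' One-sided Wilcoxon test of FPRs against a threshold
#'
#' One-sample Wilcoxon signed-rank test of the per-feature FPRs with
#' alternative "greater than `threshold`". Values tied at the threshold are
#' dropped per the signed-rank convention; if every value ties, there is no
#' information and p = 1 is returned with a warning.
#'
#' @param roi_fprs Per-feature FPRs in percent (length >= 2).
#' @param threshold Acceptability threshold in percent (default 5).
#' @return One-sided p-value.
#' @export
wilcoxon_exceeds_threshold <- function(roi_fprs, threshold = 5) {
  if (length(roi_fprs) < 2L) stop("need at least 2 FPRs", call. = FALSE)
  if (all(roi_fprs == threshold)) {
    warning("all FPRs equal the threshold: no information")
    return(1)
  }
  # drop values tied at the threshold (signed-rank convention) so the exact
  # null distribution is used whenever the remaining values allow it
  roi_fprs <- roi_fprs[roi_fprs != threshold]
  suppressWarnings(
    stats::wilcox.test(roi_fprs, mu = threshold,
                       alternative = "greater")$p.value)
}
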
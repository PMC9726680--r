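#' @title Longitudinal ComBat harmonization
#' @description
#' Per-feature linear mixed model with subject-specific random intercept
#' (optionally plus a random slope over time), scanner fixed effects under a
#' weighted sum-to-zero constraint, followed by empirical-Bayes adjustment
#' of the additive/multiplicative scanner effects on the standardized
#' residual scale. The EB kernel is shared with the cross-sectional
#' harmonizer so both methods shrink with identical machinery.
#' @name combat_long
NULL

.ranef_specs <- c("intercept_only", "intercept_slope")

# assemble the per-feature modelling frame
.lmm_frame <- function(ft, feature, covariates) {
  Y <- ft_matrix(ft)
  if (!feature %in% rownames(Y)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  df <- data.frame(
    value = Y[feature, ],
    subject = factor(ft$records$subject_id),
    scanner = factor(ft$records$scanner_id),
    time_years = ft$records$days_since_first_scan / 365.25,
    stringsAsFactors = FALSE
  )
  X <- ft_covariate_matrix(ft, covariates)
  if (!is.null(X)) {
    # center (intercept = adjusted mean) and scale to unit SD so the
    # optimizer sees comparable magnitudes; the fitted contribution X beta
    # is invariant to the scaling
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
    colnames(X) <- paste0("cov_", seq_len(ncol(X)))
    df <- cbind(df, X)
  }
  df
}

#' Fit the longitudinal mixed model for one feature
#'
#' REML fit of `value ~ covariates + scanner + (1 | subject)` (or
#' `(1 + time | subject)` for `ranef = "intercept_slope"`), with the
#' scanner contrasts re-expressed under the weighted sum-to-zero constraint
#' so that `sum(n_i * gamma_raw) == 0`. Time is days since the subject's
#' first scan divided by 365.25 (years). When every subject has a single
#' scan the random intercept is inestimable and the model degenerates to
#' ordinary least squares with the subject variance fixed at its boundary
#' value of zero (a warning is emitted).
#'
#' @param ft A [feature_table()].
#' @param feature Feature name (row of [ft_matrix()]).
#' @param covariates Covariate columns, as in [fit_standardization()].
#' @param ranef `"intercept_only"` or `"intercept_slope"`.
#' @param batch_col Record column with the batch label.
#' @return A list of class `longcombat_fit`: `alpha` (grand adjusted mean),
#'   `beta`, `gamma_raw` (per-scanner offsets, feature units, weighted
#'   sum-to-zero), `sigma_e` (REML residual SD), `varcomp` (subject
#'   intercept variance, optional slope variance/covariance), `cov_part`,
#'   `random_part` (per-scan fixed-covariate and BLUP contributions),
#'   `singular` flag and the `ranef` spec.
#' @export
fit_feature_lmm <- function(ft, feature, covariates = NULL,
                            ranef = c("intercept_only", "intercept_slope"),
                            batch_col = "scanner_id") {
  ranef <- match.arg(ranef)
  df <- .lmm_frame(ft, feature, covariates)
  if (batch_col != "scanner_id") {
    df$scanner <- factor(ft$records[[batch_col]])
  }
  n_i <- table(df$scanner)
  if (nlevels(df$scanner) < 2L) {
    stop("harmonization requires at least 2 scanners", call. = FALSE)
  }
  if (any(n_i < 2L)) {
    stop("scanner(s) with a single scan (multiplicative effect inestimable): ",
         paste(names(n_i)[n_i < 2L], collapse = ", "), call. = FALSE)
  }
  cov_terms <- grep("^cov_", names(df), value = TRUE)
  fixed_rhs <- paste(c(cov_terms, "scanner"), collapse = " + ")

  singleton <- max(table(df$subject)) == 1L
  singular <- FALSE
  if (singleton) {
    warning("every subject has a single scan: subject variance fixed at ",
            "its boundary value 0 (ordinary least squares)", call. = FALSE)
    fit <- stats::lm(stats::as.formula(paste("value ~", fixed_rhs)), df)
    fixefs <- stats::coef(fit)
    sigma_e <- stats::sigma(fit)
    varcomp <- c(subject_intercept = 0)
    random_part <- rep(0, nrow(df))
    singular <- TRUE
  } else {
    re_term <- if (ranef == "intercept_only") "(1 | subject)"
               else "(1 + time_years | subject)"
    form <- stats::as.formula(paste("value ~", fixed_rhs, "+", re_term))
    fit <- withCallingHandlers(
      lme4::lmer(form, df, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.nobs.vs.nlev = "ignore",
                   check.nobs.vs.nRE = "ignore")),
      message = function(m) invokeRestart("muffleMessage"))
    if (lme4::isSingular(fit)) {
      singular <- TRUE
      warning("singular fit for feature ", feature,
              ": variance component at boundary; proceeding", call. = FALSE)
    }
    fixefs <- lme4::fixef(fit)
    sigma_e <- stats::sigma(fit)
    vc <- lme4::VarCorr(fit)$subject
    varcomp <- c(subject_intercept = unname(vc["(Intercept)", "(Intercept)"]))
    re <- lme4::ranef(fit)$subject
    b0 <- re[as.character(df$subject), "(Intercept)"]
    random_part <- b0
    if (ranef == "intercept_slope") {
      varcomp <- c(varcomp,
                   subject_slope = unname(vc["time_years", "time_years"]),
                   intercept_slope_cov = unname(vc["(Intercept)", "time_years"]))
      random_part <- random_part +
        re[as.character(df$subject), "time_years"] * df$time_years
    }
  }

  # split fixed effects into covariate part and constrained scanner offsets
  lev <- levels(df$scanner)
  c_i <- c(0, fixefs[paste0("scanner", lev[-1])])
  names(c_i) <- lev
  wbar <- sum(as.numeric(n_i) * c_i) / nrow(df)
  gamma_raw <- c_i - wbar
  alpha <- unname(fixefs["(Intercept)"]) + wbar
  beta <- fixefs[cov_terms]
  cov_part <- if (length(cov_terms) > 0) {
    as.numeric(as.matrix(df[cov_terms]) %*% beta)
  } else rep(0, nrow(df))

  structure(list(
    feature = feature, alpha = alpha, beta = beta, gamma_raw = gamma_raw,
    sigma_e = sigma_e, varcomp = varcomp, cov_part = cov_part,
    random_part = random_part, scanner = df$scanner, n_i = n_i,
    value = df$value, ranef = ranef, singular = singular
  ), class = "longcombat_fit")
}

#' Harmonize a feature table with longitudinal ComBat
#'
#' For each feature: fit the subject-level mixed model
#' ([fit_feature_lmm()]), remove fixed covariate effects and predicted
#' random effects, standardize the remainder, estimate per-scanner
#' additive/multiplicative effects on that scale, shrink them with the
#' shared empirical-Bayes kernel, and reconstruct
#' \deqn{y^* = \sigma_v (z - \gamma^*_{iv}) / \delta^*_{iv} + \alpha_v +
#'   X\beta_v + Z b_j.}
#' The standardization SD is the divisor-N root mean square of the
#' within-scanner residuals, consistent with the cross-sectional kernel, so
#' the two methods agree in the degenerate single-scan-per-subject case.
#'
#' @inheritParams fit_feature_lmm
#' @param eb Apply empirical-Bayes shrinkage (default TRUE).
#' @param parametric Parametric prior (default TRUE).
#' @return A `feature_table` with identical rows, ordering and annotations;
#'   fitted per-feature models and scanner-effect estimates attached as
#'   attribute `"model"`.
#' @export
harmonize_longcombat <- function(ft, covariates = NULL,
                                 ranef = c("intercept_only", "intercept_slope"),
                                 batch_col = "scanner_id",
                                 eb = TRUE, parametric = TRUE) {
  ranef <- match.arg(ranef)
  Y <- ft_matrix(ft)
  feats <- rownames(Y)
  N <- ncol(Y)

  fits <- lapply(feats, function(f) {
    fit_feature_lmm(ft, f, covariates, ranef, batch_col)
  })
  names(fits) <- feats
  batch <- fits[[1]]$scanner
  lev <- levels(batch)

  z <- matrix(NA_real_, length(feats), N, dimnames = dimnames(Y))
  base_part <- z
  sigma_std <- stats::setNames(numeric(length(feats)), feats)
  gamma_hat <- matrix(NA_real_, length(lev), length(feats),
                      dimnames = list(lev, feats))
  delta_hat_sq <- gamma_hat

  for (v in seq_along(feats)) {
    f <- fits[[v]]
    m <- f$alpha + f$cov_part + f$random_part
    r <- Y[v, ] - m
    g_row <- f$gamma_raw[as.character(batch)]
    s <- sqrt(mean((r - g_row)^2))      # divisor N, as in the cross-sectional kernel
    if (s <= 0) stop("zero residual variance for feature ", feats[v],
                     call. = FALSE)
    z[v, ] <- r / s
    base_part[v, ] <- m
    sigma_std[v] <- s
    gamma_hat[, v] <- f$gamma_raw / s
    for (b in lev) {
      delta_hat_sq[b, v] <- stats::var(z[v, batch == b] - gamma_hat[b, v])
    }
  }

  if (eb) {
    priors <- .eb_hyperpriors(gamma_hat, delta_hat_sq)
    ebs <- if (parametric) {
      .eb_parametric(z, batch, gamma_hat, delta_hat_sq, priors)
    } else {
      .eb_nonparametric(z, batch, gamma_hat, delta_hat_sq)
    }
    g_use <- ebs$gamma_star
    d_use <- ebs$delta_star_sq
  } else {
    priors <- NULL
    g_use <- gamma_hat
    d_use <- delta_hat_sq
  }

  Y_adj <- z
  for (b in lev) {
    idx <- which(batch == b)
    Y_adj[, idx] <- sweep(
      sweep(z[, idx, drop = FALSE], 1, g_use[b, ]),
      1, sqrt(d_use[b, ]), `/`)
  }
  Y_adj <- Y_adj * sigma_std + base_part

  out <- ft_with_matrix(ft, Y_adj, validate = FALSE)
  attr(out, "model") <- list(
    fits = fits, gamma_hat = gamma_hat, delta_hat_sq = delta_hat_sq,
    gamma_star = if (eb) g_use else NULL,
    delta_star_sq = if (eb) d_use else NULL,
    sigma_std = sigma_std, hyperpriors = priors,
    settings = list(covariates = covariates, ranef = ranef, eb = eb,
                    parametric = parametric))
  out
}
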
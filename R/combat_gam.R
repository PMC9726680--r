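#' @title ComBat with penalized-spline covariate adjustment
#' @description
#' Identical to the cross-sectional harmonizer except that designated
#' covariates (typically age) enter the standardization model as penalized
#' smooth functions instead of linear terms. Smooths are cubic B-splines
#' with a second-difference penalty; the smoothing parameter is chosen by
#' generalized cross-validation, so the fit reduces to a straight line when
#' the data support no curvature. Smooth covariate fits are computed on the
#' pooled data before scanner-effect estimation (two-stage structure).
#' @name combat_gam
NULL

#' Fit a penalized cubic B-spline smoother
#'
#' Cubic B-spline basis with second-order difference penalty, smoothing
#' parameter selected by generalized cross-validation (via \pkg{mgcv}).
#' The penalty null space is the linear function, so exactly linear
#' relationships are recovered as straight lines and the infinite-penalty
#' limit equals the ordinary least squares line.
#'
#' @param x Covariate values (>= `basis_size` distinct values; fewer
#'   triggers basis reduction with a warning, a constant `x` is an error).
#' @param y Response (partial residuals).
#' @param basis_size Basis dimension (default 10, minimum 4).
#' @param sp Optional fixed smoothing parameter overriding GCV.
#' @return List of class `penalized_spline`: `predict(newx)`, `edf`
#'   (effective degrees of freedom), `sp` (selected smoothing parameter)
#'   and `fitted`.
#' @export
fit_penalized_spline <- function(x, y, basis_size = 10, sp = NULL) {
  stopifnot(length(x) == length(y), basis_size >= 4)
  n_distinct <- length(unique(x))
  if (n_distinct < 2L) stop("constant covariate: cannot fit a smooth",
                            call. = FALSE)
  if (n_distinct < basis_size) {
    warning("only ", n_distinct, " distinct covariate values; basis reduced",
            call. = FALSE)
    basis_size <- max(4L, n_distinct)
  }
  df <- data.frame(x = x, y = y)
  form <- y ~ s(x, bs = "ps", k = basis_size, m = c(2, 2))
  fit <- if (is.null(sp)) {
    mgcv::gam(form, data = df, method = "GCV.Cp")
  } else {
    mgcv::gam(form, data = df, method = "GCV.Cp", sp = sp)
  }
  structure(list(
    predict = function(newx) {
      as.numeric(mgcv::predict.gam(fit, newdata = data.frame(x = newx)))
    },
    edf = sum(fit$edf) + 1,   # + intercept
    sp = unname(fit$sp),
    fitted = as.numeric(stats::fitted(fit)),
    gam = fit
  ), class = "penalized_spline")
}

# pooled covariate model for one feature: smooths + linear terms
.gam_cov_fit <- function(y, X, smooth_terms, basis_size) {
  df <- as.data.frame(X)
  df$.y <- y
  lin <- setdiff(colnames(X), smooth_terms)
  sm <- vapply(smooth_terms, function(v) {
    k <- min(basis_size, length(unique(df[[v]])))
    if (k < 4) stop("covariate ", v, " has too few distinct values for a smooth",
                    call. = FALSE)
    sprintf("s(%s, bs = 'ps', k = %d, m = c(2, 2))", v, k)
  }, character(1))
  rhs <- paste(c(sm, lin), collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  fit <- mgcv::gam(form, data = df, method = "GCV.Cp")
  list(fitted = as.numeric(stats::fitted(fit)), fit = fit)
}

#' Harmonize a feature table with GAM-covariate ComBat
#'
#' Two-stage procedure per feature: (1) fit the pooled covariate model with
#' penalized-spline terms for `smooth_terms` and linear terms for the
#' remaining covariates; (2) run the cross-sectional ComBat kernel
#' (standardization, parametric empirical Bayes, scanner-effect removal) on
#' the covariate-model residuals, then restore the fitted covariate
#' surface. With no smooth terms the call reduces exactly to
#' [harmonize_neurocombat()].
#'
#' @inheritParams harmonize_neurocombat
#' @param smooth_terms Covariate names modelled as penalized smooths
#'   (default `"age_years"`); must be a subset of `covariates`.
#' @param basis_size Spline basis dimension (default 10).
#' @return A `feature_table`; fitted models attached as attribute `"model"`.
#' @export
harmonize_gamcombat <- function(ft, covariates = NULL,
                                smooth_terms = "age_years",
                                basis_size = 10,
                                batch_col = "scanner_id",
                                eb = TRUE, parametric = TRUE) {
  smooth_terms <- intersect(smooth_terms, covariates)
  if (length(smooth_terms) == 0L) {
    return(harmonize_neurocombat(ft, covariates, batch_col,
                                 eb = eb, parametric = parametric))
  }
  Y <- ft_matrix(ft)
  X <- ft_covariate_matrix(ft, covariates)

  cov_fits <- vector("list", nrow(Y))
  R <- Y
  for (v in seq_len(nrow(Y))) {
    cf <- .gam_cov_fit(Y[v, ], X, smooth_terms, basis_size)
    cov_fits[[v]] <- cf$fit
    R[v, ] <- Y[v, ] - cf$fitted
  }

  st <- .combat_standardize(R, ft$records[[batch_col]], X = NULL)
  if (eb) {
    priors <- .eb_hyperpriors(st$gamma_hat, st$delta_hat_sq)
    ebs <- if (parametric) {
      .eb_parametric(st$z, st$batch, st$gamma_hat, st$delta_hat_sq, priors)
    } else {
      .eb_nonparametric(st$z, st$batch, st$gamma_hat, st$delta_hat_sq)
    }
    g_use <- ebs$gamma_star
    d_use <- ebs$delta_star_sq
  } else {
    priors <- NULL
    g_use <- st$gamma_hat
    d_use <- st$delta_hat_sq
  }

  R_adj <- st$z
  for (b in levels(st$batch)) {
    idx <- which(st$batch == b)
    R_adj[, idx] <- sweep(
      sweep(st$z[, idx, drop = FALSE], 1, g_use[b, ]),
      1, sqrt(d_use[b, ]), `/`)
  }
  R_adj <- R_adj * st$sigma + st$stand_mean
  Y_adj <- (Y - R) + R_adj       # restore the covariate surface

  out <- ft_with_matrix(ft, Y_adj, validate = FALSE)
  attr(out, "model") <- list(
    cov_fits = cov_fits, standardization = st, hyperpriors = priors,
    gamma_star = if (eb) g_use else NULL,
    delta_star_sq = if (eb) d_use else NULL,
    settings = list(covariates = covariates, smooth_terms = smooth_terms,
                    basis_size = basis_size, eb = eb, parametric = parametric))
  out
}
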
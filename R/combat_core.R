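#' @title Cross-sectional ComBat harmonization
#' @description
#' Location-scale harmonization of feature tables across scanners. Each
#' feature is modelled as covariate effects plus an additive scanner offset
#' gamma and a multiplicative scanner scale delta; per-scanner estimates are
#' stabilized by empirical-Bayes shrinkage toward moment-matched priors
#' (normal for gamma, inverse-gamma for delta^2), either parametric
#' (conditional posterior iteration) or non-parametric (likelihood-weighted
#' averaging over the other features' estimates).
#' @name combat_core
NULL

# ---- internal kernel ------------------------------------------------------

# one-hot + centered-covariate OLS standardization shared by the
# cross-sectional and spline-covariate harmonizers.
# Y: features x scans matrix; batch: factor length N; X: N x p or NULL.
.combat_standardize <- function(Y, batch, X = NULL) {
  batch <- droplevels(as.factor(batch))
  n_i <- table(batch)
  if (nlevels(batch) < 2L) {
    stop("harmonization requires at least 2 scanners", call. = FALSE)
  }
  if (any(n_i < 2L)) {
    stop("scanner(s) with a single scan (multiplicative effect inestimable): ",
         paste(names(n_i)[n_i < 2L], collapse = ", "), call. = FALSE)
  }
  N <- ncol(Y)
  onehot <- stats::model.matrix(~ 0 + batch)
  colnames(onehot) <- levels(batch)
  centers <- NULL
  Xc <- NULL
  if (!is.null(X)) {
    X <- as.matrix(X)
    centers <- colMeans(X)
    Xc <- sweep(X, 2, centers)
  }
  D <- cbind(onehot, Xc)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- setdiff(colnames(D), colnames(D)[qrD$pivot[seq_len(qrD$rank)]])
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- solve(crossprod(D), crossprod(D, t(Y)))       # (I+p) x V
  I <- nlevels(batch)
  gamma_raw <- B[seq_len(I), , drop = FALSE]          # I x V
  beta <- if (ncol(D) > I) B[-seq_len(I), , drop = FALSE] else NULL
  w <- as.numeric(n_i) / N
  alpha <- as.numeric(crossprod(gamma_raw, w))        # length V

  fitted <- t(D %*% B)                                # V x N
  var_pooled <- rowMeans((Y - fitted)^2)              # divisor N
  if (any(var_pooled <= 0)) {
    stop("zero pooled residual variance for feature(s): ",
         paste(rownames(Y)[var_pooled <= 0], collapse = ", "), call. = FALSE)
  }
  sigma <- sqrt(var_pooled)

  stand_mean <- matrix(alpha, nrow(Y), N)
  if (!is.null(beta)) stand_mean <- stand_mean + t(Xc %*% beta)
  z <- (Y - stand_mean) / sigma

  gamma_hat <- sweep(sweep(gamma_raw, 2, alpha), 2, sigma, `/`)  # I x V
  delta_hat_sq <- t(vapply(levels(batch), function(b) {
    apply(z[, batch == b, drop = FALSE], 1, stats::var)
  }, numeric(nrow(Y))))
  if (nrow(Y) == 1L) {    # vapply collapses to a column otherwise
    delta_hat_sq <- matrix(delta_hat_sq, nrow = I, ncol = 1L,
                           dimnames = list(levels(batch), rownames(Y)))
  }
  dimnames(gamma_hat) <- list(levels(batch), rownames(Y))
  dimnames(delta_hat_sq) <- dimnames(gamma_hat)

  list(alpha = alpha, beta = beta, sigma = sigma, centers = centers,
       stand_mean = stand_mean, z = z, batch = batch, n_i = n_i,
       gamma_hat = gamma_hat, delta_hat_sq = delta_hat_sq)
}

# moment-matched priors per batch: normal on gamma, inverse-gamma on delta^2
.eb_hyperpriors <- function(gamma_hat, delta_hat_sq) {
  if (ncol(gamma_hat) < 2L) {
    stop("empirical-Bayes priors need at least 2 features; use eb = FALSE",
         call. = FALSE)
  }
  gamma_bar <- rowMeans(gamma_hat)
  tau_sq <- apply(gamma_hat, 1, stats::var)
  m <- rowMeans(delta_hat_sq)
  s2 <- apply(delta_hat_sq, 1, stats::var)
  # inverse-gamma moment matching: mean = theta/(lambda-1),
  # var = theta^2 / ((lambda-1)^2 (lambda-2))
  lambda <- (2 * s2 + m^2) / s2
  theta <- (m * s2 + m^3) / s2
  # degenerate spread across features: point prior at the common value
  flat <- !is.finite(lambda) | s2 < 1e-12 * pmax(m^2, 1)
  lambda[flat] <- 1e8
  theta[flat] <- m[flat] * (1e8 - 1)
  list(gamma_bar = gamma_bar, tau_sq = tau_sq, lambda = lambda, theta = theta)
}

# parametric EB: iterate conditional posterior means until convergence
.eb_parametric <- function(z, batch, gamma_hat, delta_hat_sq, priors,
                           tol = 1e-4, max_iter = 1000L) {
  gamma_star <- gamma_hat
  delta_star_sq <- delta_hat_sq
  for (b in seq_len(nrow(gamma_hat))) {
    lev <- rownames(gamma_hat)[b]
    zi <- z[, batch == lev, drop = FALSE]   # V x n_i
    n <- ncol(zi)
    g_hat <- gamma_hat[b, ]
    t2 <- priors$tau_sq[b]; g_bar <- priors$gamma_bar[b]
    lam <- priors$lambda[b]; th <- priors$theta[b]
    g_old <- g_hat
    d_old <- delta_hat_sq[b, ]
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      if (is.infinite(t2)) {
        g_new <- g_hat
      } else {
        g_new <- (n * t2 * g_hat + d_old * g_bar) / (n * t2 + d_old)
      }
      sum2 <- rowSums((zi - g_new)^2)
      d_new <- (th + 0.5 * sum2) / (n / 2 + lam - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < tol) { conv <- TRUE; break }
    }
    if (!conv) {
      stop(sprintf(
        "parametric EB did not converge for scanner %s (last change %.3g)",
        lev, change), call. = FALSE)
    }
    gamma_star[b, ] <- g_old
    delta_star_sq[b, ] <- d_old
  }
  list(gamma_star = gamma_star, delta_star_sq = delta_star_sq)
}

# non-parametric EB: posterior means under the empirical prior formed by the
# other features' (gamma_hat, delta_hat_sq); Monte-Carlo integration over
# that discrete prior with Gaussian likelihood weights, leave-one-out.
.eb_nonparametric <- function(z, batch, gamma_hat, delta_hat_sq) {
  V <- ncol(gamma_hat)
  if (V < 2L) {
    stop("non-parametric EB needs at least 2 features", call. = FALSE)
  }
  gamma_star <- gamma_hat
  delta_star_sq <- delta_hat_sq
  for (b in seq_len(nrow(gamma_hat))) {
    lev <- rownames(gamma_hat)[b]
    zi <- z[, batch == lev, drop = FALSE]
    n <- ncol(zi)
    g <- gamma_hat[b, ]; d <- delta_hat_sq[b, ]
    for (v in seq_len(V)) {
      x <- zi[v, ]
      gj <- g[-v]; dj <- d[-v]
      ss <- vapply(gj, function(gg) sum((x - gg)^2), numeric(1))
      loglik <- -n / 2 * log(2 * pi * dj) - ss / (2 * dj)
      wgt <- exp(loglik - max(loglik))
      wgt <- wgt / sum(wgt)
      gamma_star[b, v] <- sum(wgt * gj)
      delta_star_sq[b, v] <- sum(wgt * dj)
    }
  }
  list(gamma_star = gamma_star, delta_star_sq = delta_star_sq)
}

# ---- exported surface -----------------------------------------------------

#' Fit the ComBat standardization model
#'
#' Ordinary least squares of each feature on mean-centered covariates plus
#' scanner indicators. The per-scanner additive estimates satisfy the
#' weighted sum-to-zero constraint (sum over scanners of n_i * gamma_hat is
#' zero per feature), so the intercept `alpha` is the grand
#' covariate-adjusted mean. The pooled residual SD `sigma` uses divisor N;
#' the within-scanner variance of standardized data (`delta_hat_sq`) uses
#' the unbiased n_i - 1 divisor.
#'
#' @param ft A [feature_table()].
#' @param covariates Character vector of record columns to adjust for
#'   (see [ft_covariate_matrix()]), or `NULL`.
#' @param batch_col Record column holding the batch label (default
#'   `"scanner_id"`).
#' @return An object of class `combat_model` with elements `alpha`, `beta`,
#'   `sigma`, `gamma_hat`, `delta_hat` (SD scale), `z`, `stand_mean`,
#'   `batch`, `n_i`, and `settings`.
#' @export
fit_standardization <- function(ft, covariates = NULL,
                                batch_col = "scanner_id") {
  Y <- ft_matrix(ft)
  X <- ft_covariate_matrix(ft, covariates)
  st <- .combat_standardize(Y, ft$records[[batch_col]], X)
  structure(
    c(st, list(
      delta_hat = sqrt(st$delta_hat_sq),
      gamma_star = NULL, delta_star = NULL, hyperpriors = NULL,
      settings = list(covariates = covariates, batch_col = batch_col,
                      eb = NA, parametric = NA))),
    class = "combat_model")
}

#' Estimate empirical-Bayes hyperpriors across features
#'
#' Method of moments across features, per scanner: `gamma_bar` and `tau_sq`
#' are the mean and (n-1) variance of the additive estimates; `lambda` and
#' `theta` match an inverse-gamma to the mean and variance of the squared
#' multiplicative estimates.
#'
#' @param model A `combat_model` from [fit_standardization()].
#' @return The model with a `hyperpriors` element
#'   (`gamma_bar`, `tau_sq`, `lambda`, `theta`, one entry per scanner).
#' @export
estimate_hyperpriors <- function(model) {
  stopifnot(inherits(model, "combat_model"))
  model$hyperpriors <- .eb_hyperpriors(model$gamma_hat, model$delta_hat_sq)
  model
}

#' Empirical-Bayes shrinkage of scanner effects
#'
#' Parametric path: iterate the conditional posterior updates
#' \deqn{\gamma^* = (n_i \tau^2 \hat\gamma + \delta^{*2} \bar\gamma) /
#'       (n_i \tau^2 + \delta^{*2})}
#' \deqn{\delta^{*2} = (\theta + \tfrac12 \sum_j (z - \gamma^*)^2) /
#'       (n_i/2 + \lambda - 1)}
#' until the maximum absolute parameter change drops below `tol`.
#' Non-parametric path: each feature's shrunken pair is the
#' likelihood-weighted average of the other features' raw estimates.
#'
#' @param model A `combat_model` with hyperpriors (parametric path), or at
#'   least raw estimates (non-parametric path).
#' @param parametric Use the parametric (normal / inverse-gamma) prior?
#' @param tol,max_iter Convergence control for the parametric iteration.
#' @return The model with `gamma_star` and `delta_star` (SD scale) filled.
#' @export
eb_shrink <- function(model, parametric = TRUE, tol = 1e-4, max_iter = 1000L) {
  stopifnot(inherits(model, "combat_model"))
  if (parametric) {
    if (is.null(model$hyperpriors)) model <- estimate_hyperpriors(model)
    eb <- .eb_parametric(model$z, model$batch, model$gamma_hat,
                         model$delta_hat_sq, model$hyperpriors,
                         tol = tol, max_iter = max_iter)
  } else {
    eb <- .eb_nonparametric(model$z, model$batch, model$gamma_hat,
                            model$delta_hat_sq)
  }
  model$gamma_star <- eb$gamma_star
  model$delta_star <- sqrt(eb$delta_star_sq)
  model$settings$eb <- TRUE
  model$settings$parametric <- parametric
  model
}

# apply (possibly shrunken) scanner effects to produce adjusted values
.combat_apply <- function(model, Y) {
  if (isTRUE(model$settings$eb)) {
    g <- model$gamma_star
    d_sq <- model$delta_star^2
  } else {
    g <- model$gamma_hat
    d_sq <- model$delta_hat_sq
  }
  z_adj <- model$z
  for (b in levels(model$batch)) {
    idx <- model$batch == b
    z_adj[, idx] <- (model$z[, idx, drop = FALSE] - g[b, ]) / sqrt(d_sq[b, ])
  }
  z_adj * model$sigma + model$stand_mean
}

#' Harmonize a feature table with cross-sectional ComBat
#'
#' Full pipeline: standardization ([fit_standardization()]), optional
#' empirical-Bayes shrinkage ([eb_shrink()]), then reconstruction
#' \deqn{y^* = \sigma_v (z - \gamma^*_{iv}) / \delta^*_{iv} + \alpha_v +
#'       X\beta_v.}
#' With `eb = FALSE` the raw per-scanner estimates are removed
#' (location-shift model). Covariate relationships are preserved: re-fitting
#' the covariate model on the output recovers the same coefficients up to
#' numerical tolerance.
#'
#' @inheritParams fit_standardization
#' @param eb Apply empirical-Bayes shrinkage (default TRUE).
#' @param parametric Parametric prior (default TRUE); ignored when
#'   `eb = FALSE`.
#' @return A `feature_table` of identical shape and annotations; the fitted
#'   `combat_model` is attached as attribute `"model"`.
#' @export
#' @examples
#' sim <- simulate_cohort(make_scenario("scanner_effect", seed = 7))
#' harm <- harmonize_neurocombat(sim$table,
#'   covariates = c("age_years", "sex", "icv", "days_since_first_scan"))
harmonize_neurocombat <- function(ft, covariates = NULL,
                                  batch_col = "scanner_id",
                                  eb = TRUE, parametric = TRUE) {
  model <- fit_standardization(ft, covariates, batch_col)
  if (eb) {
    model <- eb_shrink(model, parametric = parametric)
  } else {
    model$settings$eb <- FALSE
  }
  Y_adj <- .combat_apply(model, ft_matrix(ft))
  out <- ft_with_matrix(ft, Y_adj, validate = FALSE)
  attr(out, "model") <- model
  out
}
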
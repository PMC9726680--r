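# straight-line re-implementation of the location-scale adjustment used as
# an independent oracle: no covariates, loops and explicit formulas only
oracle_combat <- function(Y, batch, eb = FALSE, parametric = TRUE,
                          tol = 1e-10) {
  lev <- sort(unique(batch))
  N <- ncol(Y); V <- nrow(Y)
  n_i <- sapply(lev, function(b) sum(batch == b))
  gamma_raw <- matrix(NA_real_, length(lev), V)
  for (b in seq_along(lev)) for (v in seq_len(V)) {
    gamma_raw[b, v] <- mean(Y[v, batch == lev[b]])
  }
  alpha <- as.numeric(t(gamma_raw) %*% (n_i / N))
  var_pooled <- numeric(V)
  for (v in seq_len(V)) {
    res <- Y[v, ] - gamma_raw[match(batch, lev), v]
    var_pooled[v] <- sum(res^2) / N
  }
  sigma <- sqrt(var_pooled)
  z <- (Y - alpha) / sigma
  g_hat <- matrix(NA_real_, length(lev), V)
  d_hat_sq <- g_hat
  for (b in seq_along(lev)) for (v in seq_len(V)) {
    zi <- z[v, batch == lev[b]]
    g_hat[b, v] <- (gamma_raw[b, v] - alpha[v]) / sigma[v]
    d_hat_sq[b, v] <- sum((zi - mean(zi))^2) / (n_i[b] - 1)
  }
  g_use <- g_hat; d_use <- d_hat_sq
  if (eb && parametric) {
    for (b in seq_along(lev)) {
      g_bar <- mean(g_hat[b, ])
      t2 <- sum((g_hat[b, ] - g_bar)^2) / (V - 1)
      m <- mean(d_hat_sq[b, ])
      s2 <- sum((d_hat_sq[b, ] - m)^2) / (V - 1)
      lam <- (2 * s2 + m^2) / s2
      th <- (m * s2 + m^3) / s2
      g_old <- g_hat[b, ]; d_old <- d_hat_sq[b, ]
      repeat {
        g_new <- (n_i[b] * t2 * g_hat[b, ] + d_old * g_bar) /
          (n_i[b] * t2 + d_old)
        d_new <- numeric(V)
        for (v in seq_len(V)) {
          d_new[v] <- (th + 0.5 * sum((z[v, batch == lev[b]] - g_new[v])^2)) /
            (n_i[b] / 2 + lam - 1)
        }
        if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-4) break
        g_old <- g_new; d_old <- d_new
      }
      g_use[b, ] <- g_new; d_use[b, ] <- d_new
    }
  }
  Yadj <- Y
  for (v in seq_len(V)) for (j in seq_len(N)) {
    b <- match(batch[j], lev)
    Yadj[v, j] <- sigma[v] * (z[v, j] - g_use[b, v]) / sqrt(d_use[b, v]) +
      alpha[v]
  }
  Yadj
}
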
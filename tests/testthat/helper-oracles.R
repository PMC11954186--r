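# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive re-derivation (enumeration, grid search, resampling)
# that shares no code path with the implementation it checks.

# Quartile by direct order-statistic interpolation (linear between order
# statistics, the type-7 convention), written out longhand.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Loop-based k*IQR-from-the-median keep mask.
oracle_iqr_mask <- function(values, k = 4) {
  med <- oracle_quantile(values, 0.5)
  iqr <- oracle_quantile(values, 0.75) - oracle_quantile(values, 0.25)
  keep <- logical(length(values))
  for (i in seq_along(values)) {
    keep[i] <- if (iqr == 0) values[i] == med else
      abs(values[i] - med) <= k * iqr
  }
  keep
}

# Brute-force sinusoid fit: 2-D grid over (amplitude, acrophase) with the
# intercept profiled out, refined twice around the incumbent.
oracle_grid_cosinor <- function(y, month, n_grid = 60, refinements = 2) {
  theta <- 2 * pi * (month - 1) / 12
  a_max <- max(2 * stats::sd(y), 1e-3)
  a_range <- c(0, a_max)
  p_range <- c(-pi, pi)
  best <- c(A = NA, phi = NA, b0 = NA, rss = Inf)
  for (r in 0:refinements) {
    As <- seq(a_range[1], a_range[2], length.out = n_grid)
    phis <- seq(p_range[1], p_range[2], length.out = n_grid)
    for (A in As) for (phi in phis) {
      s <- A * cos(theta - phi)
      b0 <- mean(y - s)
      rss <- sum((y - b0 - s)^2)
      if (rss < best["rss"]) best <- c(A = A, phi = phi, b0 = b0, rss = rss)
    }
    da <- diff(a_range) / (n_grid - 1)
    dp <- diff(p_range) / (n_grid - 1)
    a_range <- c(max(0, best["A"] - 2 * da), best["A"] + 2 * da)
    p_range <- c(best["phi"] - 2 * dp, best["phi"] + 2 * dp)
  }
  best
}

# Nonparametric bootstrap SEs for amplitude and acrophase via plain
# lm.fit refits on resampled rows.
oracle_bootstrap_se <- function(y, month, B = 1000, seed = 1) {
  theta <- 2 * pi * (month - 1) / 12
  X <- cbind(1, cos(theta), sin(theta))
  n <- length(y)
  set.seed(seed)
  amp <- phi <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    cf <- stats::lm.fit(X[idx, ], y[idx])$coefficients
    amp[b] <- sqrt(cf[2]^2 + cf[3]^2)
    phi[b] <- atan2(cf[3], cf[2])
  }
  c(amplitude = stats::sd(amp), acrophase = stats::sd(phi))
}

# Hand-built cosinor "fit" with named coefficients and diagonal
# covariance, for testing the coefficient transforms in isolation.
fake_fit <- function(b2, b3, var = c(1, 1e-4, 1e-4), b0 = 0) {
  nm <- c("(Intercept)", "cosw", "sinw")
  V <- diag(var, 3)
  dimnames(V) <- list(nm, nm)
  list(coefficients = stats::setNames(c(b0, b2, b3), nm), vcov = V)
}

# Small noiseless cohort covering all 12 months, for exact-recovery tests.
noiseless_cohort <- function(per_month = 5, b0 = 0, A = 0.5, phi = 0) {
  month <- rep(1:12, each = per_month)
  theta <- 2 * pi * (month - 1) / 12
  list(month = month, outcome = b0 + A * cos(theta - phi))
}

# Quick null-marker interaction p-values and z-scores for calibration
# tests: seasonal signal present, marker independent of the outcome.
null_interaction_stats <- function(n, A = 0.3, reps = 1, seed = 1) {
  p <- z <- matrix(NA_real_, reps, 3,
                   dimnames = list(NULL, c("amp", "acro", "disp")))
  set.seed(seed)
  for (r in seq_len(reps)) {
    month <- sample.int(12, n, replace = TRUE)
    theta <- 2 * pi * (month - 1) / 12
    y <- A * cos(theta + 0.14) + stats::rnorm(n)
    marker <- stats::rbinom(n, 1, 0.5)
    fit <- fit_interaction(y, month, marker)
    s <- as.data.frame(summarize_interaction(fit))
    p[r, ] <- s$p_value
    z[r, ] <- s$t_score
  }
  list(p = p, z = z)
}
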
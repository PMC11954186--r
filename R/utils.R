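# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
wrap_angle <- function(phi) {
  # wrap into (-pi, pi]
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# Derive a reproducible sub-stream seed from a master seed and a module
# label, so each stage of the pipeline consumes an independent stream.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
#' @keywords internal
#' @noRd
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629)
}

# Ordinary least squares with explicit coefficient covariance.
# Errors on rank deficiency, naming the collinear columns, because a
# silently dropped seasonal or interaction term would corrupt the
# delta-method transforms downstream.
#' @keywords internal
#' @noRd
ols_fit <- function(X, y, robust = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more observations (", n, ") than coefficients (", p, ")")
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- n - p
  xtx_inv <- chol2inv(qr.R(qrx))
  # undo the pivoting applied by qr()
  piv <- qrx$pivot
  xtx_inv <- xtx_inv[order(piv), order(piv), drop = FALSE]
  if (robust) {
    # HC1 sandwich covariance
    meat <- crossprod(X * as.numeric(res))
    bread <- xtx_inv
    vcov <- bread %*% meat %*% bread * n / df
  } else {
    sigma2 <- sum(res^2) / df
    vcov <- xtx_inv * sigma2
  }
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  list(coefficients = beta, vcov = vcov,
       sigma = sqrt(sum(res^2) / df), df.residual = df, n_used = n,
       residuals = as.numeric(res), fitted = as.numeric(X %*% beta))
}

# Build a covariate model matrix from a data.frame, keeping column names
# stable. Factors/characters are expanded to treatment-coded dummies.
#' @keywords internal
#' @noRd
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop("covariates must have one row per observation")
  if (anyNA(covariates)) {
    bad <- names(covariates)[vapply(covariates, anyNA, logical(1))]
    stop("missing values in covariate(s): ", paste(bad, collapse = ", "),
         "; impute before model fitting")
  }
  mm <- stats::model.matrix(~ . - 1, data = covariates)
  # model.matrix drops a reference level only with an intercept; rebuild
  # with intercept handling done by the caller, so drop nothing here for
  # numeric columns but re-code factors against a reference level.
  if (any(vapply(covariates, function(x) is.factor(x) || is.character(x), logical(1)))) {
    mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  mm
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
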
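#' Sine-cosine seasonal basis for month of recruitment
#'
#' Maps a calendar month (January = 1 ... December = 12) onto the annual
#' harmonic basis used throughout the package:
#' \deqn{SINW = \sin(2\pi (month - 1)/12), \quad
#'       COSW = \cos(2\pi (month - 1)/12).}
#' January therefore sits at phase zero, i.e. \code{(sinw, cosw) = (0, 1)}.
#'
#' @param month integer vector with values in 1..12.
#' @return data.frame with columns \code{month}, \code{sinw}, \code{cosw}.
#' @examples
#' seasonal_basis(c(1, 4, 7))
#' @export
seasonal_basis <- function(month) {
  if (anyNA(month) || !all(month %in% 1:12)) {
    bad <- which(is.na(month) | !(month %in% 1:12))
    stop("month must be an integer in 1..12; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  theta <- 2 * pi * (month - 1) / 12
  data.frame(month = as.integer(month), sinw = sin(theta), cosw = cos(theta))
}

#' Fit the cosinor regression of an outcome on the seasonal basis
#'
#' Ordinary least squares of the (typically standardized) outcome on an
#' intercept, the cosine and sine season terms, and any adjustment
#' covariates:
#' \deqn{y = \beta_0 + \beta_2 COSW + \beta_3 SINW + \sum_i \beta_i C_i + \varepsilon.}
#' The classical homoskedastic coefficient covariance is returned by
#' default; a heteroskedasticity-robust (HC1) covariance is available via
#' \code{robust = TRUE}.
#'
#' @param outcome numeric outcome vector, no missing values.
#' @param month integer months 1..12, same length.
#' @param covariates optional data.frame of adjustment covariates
#'   (complete after imputation).
#' @param robust logical; use an HC1 sandwich covariance instead of the
#'   classical OLS covariance.
#' @return an object of class \code{cosinor_fit}: list with
#'   \code{coefficients} (named: \code{"(Intercept)"}, \code{"cosw"},
#'   \code{"sinw"}, covariates), \code{vcov}, \code{sigma},
#'   \code{df.residual}, \code{n_used}.
#' @seealso [seasonal_characteristics()] for the amplitude/acrophase
#'   transforms with delta-method standard errors.
#' @export
fit_cosinor <- function(outcome, month, covariates = NULL, robust = FALSE) {
  if (anyNA(outcome)) stop("outcome contains missing values")
  if (length(outcome) != length(month)) stop("outcome and month lengths differ")
  basis <- seasonal_basis(month)
  n <- length(outcome)
  C <- covariate_matrix(covariates, n)
  X <- cbind("(Intercept)" = 1, cosw = basis$cosw, sinw = basis$sinw, C)
  fit <- ols_fit(X, outcome, robust = robust)
  fit$robust <- robust
  class(fit) <- "cosinor_fit"
  fit
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("Cosinor fit (n =", x$n_used, ")\n")
  print(round(x$coefficients[1:3], 6))
  invisible(x)
}

#' Amplitude of the fitted seasonal wave with delta-method SE
#'
#' The amplitude is \eqn{A = \sqrt{\beta_2^2 + \beta_3^2}} with
#' \eqn{\beta_2, \beta_3} the cosine/sine coefficients. Its standard error
#' is a first-order Taylor (delta-method) propagation of the 2x2
#' coefficient sub-covariance through the transform, with gradient
#' \eqn{(\beta_2/A, \beta_3/A)}.
#'
#' Near \eqn{A = 0} the transform is non-differentiable and the
#' delta-method SE is unreliable; the result carries a \code{degenerate}
#' flag (raised when \eqn{A < 3 \max(se_{\beta_2}, se_{\beta_3})}) and the
#' joint 2-df test ([joint_seasonality_test()]) should be preferred there.
#'
#' @param fit a \code{cosinor_fit} (or any fit exposing \code{cosw}/
#'   \code{sinw} coefficients and their covariance).
#' @return list with \code{estimate}, \code{se}, \code{degenerate}.
#' @export
amplitude_estimate <- function(fit) {
  b <- fit$coefficients[c("cosw", "sinw")]
  V <- fit$vcov[c("cosw", "sinw"), c("cosw", "sinw")]
  A <- sqrt(sum(b^2))
  if (A == 0) return(list(estimate = 0, se = NA_real_, degenerate = TRUE))
  g <- c(b[["cosw"]], b[["sinw"]]) / A
  se <- sqrt(drop(t(g) %*% V %*% g))
  degenerate <- A < 3 * max(sqrt(diag(V)))
  list(estimate = A, se = se, degenerate = degenerate)
}

#' Acrophase of the fitted seasonal wave with delta-method SE
#'
#' The acrophase (phase angle of the annual peak) is the four-quadrant
#' arctangent \eqn{\varphi = \mathrm{atan2}(\beta_3, \beta_2)}, in radians
#' in \eqn{(-\pi, \pi]}. A single-argument \eqn{\arctan(\beta_3/\beta_2)}
#' is quadrant-ambiguous; the two agree whenever \eqn{\beta_2 > 0}
#' (winter-peaking patterns). The SE comes from the delta method with
#' gradient \eqn{(-\beta_3/A^2, \beta_2/A^2)}.
#'
#' @inheritParams amplitude_estimate
#' @return list with \code{estimate} (radians), \code{se}.
#' @export
acrophase_estimate <- function(fit) {
  b <- fit$coefficients[c("cosw", "sinw")]
  V <- fit$vcov[c("cosw", "sinw"), c("cosw", "sinw")]
  A2 <- sum(b^2)
  if (A2 == 0) stop("acrophase undefined: both seasonal coefficients are zero")
  phi <- atan2(b[["sinw"]], b[["cosw"]])
  g <- c(-b[["sinw"]], b[["cosw"]]) / A2
  se <- sqrt(drop(t(g) %*% V %*% g))
  list(estimate = phi, se = se)
}

#' Wald summary (T-score, 95% CI, two-sided P) for an estimate/SE pair
#'
#' Uses the standard-normal reference distribution: with the sample sizes
#' in scope the difference from the t distribution is negligible.
#'
#' @param estimate numeric estimate(s).
#' @param se positive standard error(s).
#' @param conf confidence level, default 0.95.
#' @return data.frame with \code{estimate}, \code{se}, \code{t_score},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}.
#' @export
wald_summary <- function(estimate, se, conf = 0.95) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive and finite")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  t_score <- estimate / se
  data.frame(estimate = estimate, se = se, t_score = t_score,
             ci_low = estimate - z * se, ci_high = estimate + z * se,
             p_value = 2 * stats::pnorm(-abs(t_score)))
}

#' Joint 2-df Wald test of no seasonality
#'
#' Tests \eqn{(\beta_2, \beta_3) = (0, 0)} with the quadratic form
#' \eqn{b^T \Sigma^{-1} b \sim \chi^2_2}. This test is well behaved at
#' zero amplitude, where the delta-method SE of the amplitude is not.
#'
#' @inheritParams amplitude_estimate
#' @return the P-value of the joint test.
#' @export
joint_seasonality_test <- function(fit) {
  b <- fit$coefficients[c("cosw", "sinw")]
  V <- fit$vcov[c("cosw", "sinw"), c("cosw", "sinw")]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular seasonal coefficient covariance"))
  stat <- drop(t(b) %*% Vi %*% b)
  stats::pchisq(stat, df = 2, lower.tail = FALSE)
}

#' Convert an acrophase to calendar peak and trough positions
#'
#' The fitted wave is \eqn{A\cos(\theta - \varphi)} with
#' \eqn{\theta = 2\pi(month-1)/12}, so the peak falls at
#' \eqn{month = 1 + 12\varphi/(2\pi)}, wrapped into \eqn{(0, 12]}; the
#' trough is half a year later. An acrophase of 0 peaks exactly at
#' January (month 1.0) and troughs at July (7.0).
#'
#' @param acrophase acrophase in radians.
#' @return data.frame with \code{peak_month} and \code{trough_month},
#'   months-into-the-year on the scale (0, 12].
#' @examples
#' acrophase_to_calendar(-0.14)  # trough ~ 6.7 months into the year
#' @export
acrophase_to_calendar <- function(acrophase) {
  stopifnot(all(is.finite(acrophase)))
  wrap12 <- function(m) {
    out <- m %% 12
    out[out == 0] <- 12
    out
  }
  peak <- wrap12(1 + 12 * acrophase / (2 * pi))
  data.frame(peak_month = peak, trough_month = wrap12(peak + 6))
}

#' Variance explained by a seasonal wave of given amplitude
#'
#' A sinusoid of amplitude \eqn{A} sampled uniformly over its period has
#' variance \eqn{A^2/2} (exactly so for 12 equally spaced months), so on
#' an outcome of total variance \eqn{\sigma^2} the seasonal component
#' explains \eqn{100 \cdot (A^2/2)/\sigma^2} percent. An amplitude of
#' 0.092 SD on a unit-variance outcome explains ~0.42%.
#'
#' @param amplitude non-negative amplitude, outcome SD units.
#' @param total_variance total outcome variance (default 1).
#' @return percent of variance explained.
#' @export
amplitude_variance_explained <- function(amplitude, total_variance = 1) {
  stopifnot(amplitude >= 0, total_variance > 0)
  100 * (amplitude^2 / 2) / total_variance
}

#' Seasonal characteristics (amplitude, acrophase, displacement) of a fit
#'
#' Bundles the nonlinear coefficient transforms with their delta-method
#' standard errors and Wald summaries into a one-row-per-quantity report.
#' Displacement is the model intercept (the MESOR / vertical shift of the
#' wave at covariate value zero).
#'
#' @inheritParams amplitude_estimate
#' @param conf confidence level for the Wald intervals.
#' @return object of class \code{seasonal_characteristics}: data.frame
#'   with rows \code{amplitude}, \code{acrophase}, \code{displacement}
#'   and columns \code{estimate}, \code{se}, \code{t_score},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}; attributes
#'   \code{joint_p} (2-df seasonality test), \code{degenerate},
#'   \code{peak_month}, \code{trough_month}, \code{n_used}.
#' @export
seasonal_characteristics <- function(fit, conf = 0.95) {
  amp <- amplitude_estimate(fit)
  acr <- acrophase_estimate(fit)
  disp <- list(estimate = fit$coefficients[["(Intercept)"]],
               se = sqrt(fit$vcov["(Intercept)", "(Intercept)"]))
  rows <- rbind(
    wald_summary(amp$estimate, amp$se, conf),
    wald_summary(acr$estimate, acr$se, conf),
    wald_summary(disp$estimate, disp$se, conf))
  rownames(rows) <- c("amplitude", "acrophase", "displacement")
  cal <- acrophase_to_calendar(acr$estimate)
  structure(rows,
            joint_p = joint_seasonality_test(fit),
            degenerate = amp$degenerate,
            peak_month = cal$peak_month,
            trough_month = cal$trough_month,
            n_used = fit$n_used,
            class = c("seasonal_characteristics", "data.frame"))
}

#' @export
print.seasonal_characteristics <- function(x, ...) {
  cat("Seasonal characteristics (n =", attr(x, "n_used"), ")\n")
  print.data.frame(round(as.data.frame(x), 6))
  cat(sprintf("joint seasonality P = %.3g; peak %.2f / trough %.2f months into the year\n",
              attr(x, "joint_p"), attr(x, "peak_month"), attr(x, "trough_month")))
  if (isTRUE(attr(x, "degenerate")))
    cat("note: amplitude near zero; delta-method SE unreliable, use the joint test\n")
  invisible(x)
}
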
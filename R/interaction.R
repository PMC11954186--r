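# Marker-by-season interaction models: how a marker modifies amplitude,
# acrophase and displacement of the seasonal pattern.

#' Fit the marker-by-season interaction regression
#'
#' OLS of
#' \deqn{y = \beta_0 + \beta_1 M + \beta_2 COSW + \beta_3 SINW
#'       + \beta_4 M \cdot COSW + \beta_5 M \cdot SINW + \sum_i \beta_i C_i}
#' where \eqn{M} is the investigated marker (binary exposure or linear,
#' per unit). Rows with a missing marker value are dropped for this fit
#' (the incident-disease coding sets prevalent cases to missing, so this
#' is the analysis-set definition). When \code{mutual_adjust} markers are
#' supplied (e.g. the full blood-cell panel), they enter as main effects
#' only, while the interaction is computed for \code{marker} alone.
#'
#' @param outcome numeric outcome.
#' @param month integer months 1..12.
#' @param marker numeric marker vector (NA allowed; rows dropped).
#' @param covariates optional data.frame of adjustment covariates.
#' @param mutual_adjust optional data.frame of co-markers entering as main
#'   effects only.
#' @param robust logical; HC1 covariance.
#' @return object of class \code{interaction_fit}: the full OLS fit plus
#'   \code{beta} (named \code{beta1}..\code{beta5}), \code{sub_vcov}
#'   (5x5 covariance over \eqn{\beta_1..\beta_5}), \code{n_used},
#'   \code{n_dropped}.
#' @export
fit_interaction <- function(outcome, month, marker, covariates = NULL,
                            mutual_adjust = NULL, robust = FALSE) {
  stopifnot(length(outcome) == length(month), length(marker) == length(outcome))
  keep <- !is.na(marker) & !is.na(outcome)
  n_dropped <- sum(!keep)
  outcome <- outcome[keep]; month <- month[keep]; marker <- marker[keep]
  if (length(unique(marker)) < 2)
    stop("marker is constant in the analysis set; interaction not identifiable")
  basis <- seasonal_basis(month)
  n <- length(outcome)
  C <- covariate_matrix(if (is.null(covariates)) NULL else
    covariates[keep, , drop = FALSE], n)
  Madj <- covariate_matrix(if (is.null(mutual_adjust)) NULL else
    mutual_adjust[keep, , drop = FALSE], n)
  X <- cbind("(Intercept)" = 1, marker = marker,
             cosw = basis$cosw, sinw = basis$sinw,
             "marker:cosw" = marker * basis$cosw,
             "marker:sinw" = marker * basis$sinw, C, Madj)
  fit <- ols_fit(X, outcome, robust = robust)
  idx <- c("marker", "cosw", "sinw", "marker:cosw", "marker:sinw")
  beta <- fit$coefficients[idx]
  names(beta) <- paste0("beta", 1:5)
  fit$beta <- beta
  fit$sub_vcov <- fit$vcov[idx, idx]
  fit$n_dropped <- n_dropped
  class(fit) <- c("interaction_fit", "cosinor_fit")
  fit
}

#' Summarize an interaction fit as seasonal-characteristic changes
#'
#' Transforms the interaction coefficients into the three reported
#' quantities, each with a delta-method SE, z, 95% CI and P:
#' \itemize{
#'   \item \strong{delta amplitude}: the exact difference of amplitudes
#'     with vs without the marker (per unit for a linear marker),
#'     \eqn{\sqrt{(\beta_2+\beta_4)^2 + (\beta_3+\beta_5)^2} -
#'          \sqrt{\beta_2^2+\beta_3^2}}, reported both in outcome SD units
#'     and as a signed percentage of \code{reference_amplitude};
#'   \item \strong{delta acrophase}: \eqn{\mathrm{atan2}(\beta_3+\beta_5,
#'     \beta_2+\beta_4) - \mathrm{atan2}(\beta_3, \beta_2)}, wrapped to
#'     \eqn{(-\pi, \pi]}, reported in months (x 12/2\eqn{\pi}; the
#'     percent-of-a-month convention is 100x the month value);
#'   \item \strong{displacement}: the marginal effect \eqn{\beta_1}.
#' }
#' SEs use the full four-dimensional gradient over the
#' \eqn{(\beta_2,\beta_3,\beta_4,\beta_5)} sub-covariance
#' (displacement SE directly from \eqn{\beta_1}).
#'
#' \code{method = "linearized"} instead uses the first-order projections
#' \eqn{(\beta_2\beta_4 + \beta_3\beta_5)/A} for the amplitude change and
#' \eqn{(\beta_2\beta_5 - \beta_3\beta_4)/A^2} for the acrophase change;
#' the two definitions agree to first order in small interaction effects.
#'
#' @param fit an \code{interaction_fit}.
#' @param reference_amplitude positive reference for the percent scale;
#'   default is the same model's baseline amplitude
#'   \eqn{\sqrt{\beta_2^2+\beta_3^2}}.
#' @param method \code{"exact"} (default) or \code{"linearized"}.
#' @param conf confidence level.
#' @return object of class \code{interaction_summary}: data.frame with
#'   rows \code{amplitude}, \code{acrophase}, \code{displacement};
#'   columns \code{estimate}, \code{se}, \code{z}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, \code{unit}. Attributes:
#'   \code{delta_amplitude_pct} (+ se), \code{delta_acrophase_pct_month}
#'   (+ se), \code{reference_amplitude}, \code{n_used}, \code{flag}.
#' @export
summarize_interaction <- function(fit, reference_amplitude = NULL,
                                  method = c("exact", "linearized"),
                                  conf = 0.95) {
  method <- match.arg(method)
  b <- fit$beta
  V <- fit$sub_vcov
  b2 <- b[["beta2"]]; b3 <- b[["beta3"]]
  b4 <- b[["beta4"]]; b5 <- b[["beta5"]]
  A0 <- sqrt(b2^2 + b3^2)
  A1 <- sqrt((b2 + b4)^2 + (b3 + b5)^2)
  if (A0 == 0) stop("baseline seasonal coefficients are zero; changes undefined")
  flag <- NULL
  if (A1 < .Machine$double.eps^0.5)
    flag <- "marker-present amplitude ~ 0: acrophase change ill-defined"
  V4 <- V[2:5, 2:5]  # (beta2, beta3, beta4, beta5)

  if (method == "exact") {
    dA <- A1 - A0
    gA <- c((b2 + b4) / A1 - b2 / A0,
            (b3 + b5) / A1 - b3 / A0,
            (b2 + b4) / A1,
            (b3 + b5) / A1)
    dphi <- wrap_angle(atan2(b3 + b5, b2 + b4) - atan2(b3, b2))
    gphi <- c(b3 / A0^2 - (b3 + b5) / A1^2,
              -b2 / A0^2 + (b2 + b4) / A1^2,
              -(b3 + b5) / A1^2,
              (b2 + b4) / A1^2)
  } else {
    dA <- (b2 * b4 + b3 * b5) / A0
    gA <- c(b4 / A0 - (b2 * b4 + b3 * b5) * b2 / A0^3,
            b5 / A0 - (b2 * b4 + b3 * b5) * b3 / A0^3,
            b2 / A0, b3 / A0)
    dphi <- (b2 * b5 - b3 * b4) / A0^2
    gphi <- c(b5 / A0^2 - 2 * (b2 * b5 - b3 * b4) * b2 / A0^4,
              -b4 / A0^2 - 2 * (b2 * b5 - b3 * b4) * b3 / A0^4,
              -b3 / A0^2, b2 / A0^2)
  }
  se_dA <- sqrt(drop(t(gA) %*% V4 %*% gA))
  se_dphi <- sqrt(drop(t(gphi) %*% V4 %*% gphi))
  disp <- b[["beta1"]]
  se_disp <- sqrt(V[1, 1])

  ref <- reference_amplitude %||% A0
  if (ref <= 0) stop("reference_amplitude must be positive")
  to_month <- 12 / (2 * pi)
  rows <- rbind(
    wald_summary(dA, se_dA, conf),
    wald_summary(dphi * to_month, se_dphi * to_month, conf),
    wald_summary(disp, se_disp, conf))
  rownames(rows) <- c("amplitude", "acrophase", "displacement")
  rows$unit <- c("outcome SD", "months", "outcome SD")
  structure(rows,
            delta_amplitude_pct = 100 * dA / ref,
            delta_amplitude_pct_se = 100 * se_dA / ref,
            delta_acrophase_pct_month = 100 * dphi * to_month,
            delta_acrophase_pct_month_se = 100 * se_dphi * to_month,
            reference_amplitude = ref,
            method = method,
            n_used = fit$n_used,
            flag = flag,
            class = c("interaction_summary", "data.frame"))
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat("Marker-by-season interaction (n =", attr(x, "n_used"), ")\n")
  print.data.frame(cbind(round(as.data.frame(x)[1:6], 6), unit = x$unit))
  cat(sprintf("delta amplitude: %.2f%% of reference amplitude %.4f SD\n",
              attr(x, "delta_amplitude_pct"), attr(x, "reference_amplitude")))
  if (!is.null(attr(x, "flag"))) cat("flag:", attr(x, "flag"), "\n")
  invisible(x)
}

#' Incident-disease exposure coding
#'
#' Restricts a disease exposure to incident cases: individuals with no
#' recorded event are controls (0), a first event after recruitment is an
#' incident case (1), and a prevalent case (event on or before
#' recruitment) is set to missing and thereby removed from that disease's
#' analysis set.
#'
#' @param event_date event date (Date or numeric), NA = no event.
#' @param recruit_date recruitment date, same type.
#' @return integer vector: 0, 1 or NA.
#' @export
incident_disease_exposure <- function(event_date, recruit_date) {
  stopifnot(length(event_date) == length(recruit_date))
  out <- integer(length(event_date))
  has <- !is.na(event_date)
  out[has & event_date > recruit_date] <- 1L
  out[has & event_date <= recruit_date] <- NA_integer_
  out
}

#' Composite any-disease / multiple-disease phenotypes
#'
#' From incident-coded indicator columns over major disease groups,
#' builds the "any recorded disease" and "multiple diseases" (two or
#' more groups) phenotypes. Missing group entries (prevalent cases)
#' propagate: an individual is only a definite control/single-group case
#' when the observed groups suffice to decide.
#'
#' @param groups data.frame or matrix of incident indicators (0/1/NA),
#'   one column per major disease group.
#' @return data.frame with columns \code{any_disease},
#'   \code{multiple_diseases} (0/1/NA).
#' @export
composite_disease_phenotypes <- function(groups) {
  groups <- as.matrix(groups)
  if (ncol(groups) < 1) stop("need at least one disease-group column")
  ones <- rowSums(groups == 1, na.rm = TRUE)
  nas <- rowSums(is.na(groups))
  any_d <- ifelse(ones >= 1, 1L, ifelse(nas > 0, NA_integer_, 0L))
  mult <- ifelse(ones >= 2, 1L, ifelse(ones + nas >= 2, NA_integer_, 0L))
  data.frame(any_disease = any_d, multiple_diseases = mult)
}

#' Genomic inflation factor from a P-value stream
#'
#' \eqn{\lambda_{GC}}: the median of the implied 1-df chi-square
#' statistics divided by the null median 0.4549. Well-calibrated null
#' tests give \eqn{\lambda \approx 1}; inflation > 1 signals residual
#' confounding or miscalibration.
#'
#' @param p_values P-values in (0, 1].
#' @return lambda (scalar).
#' @export
lambda_gc <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no P-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("P-values must be in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
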
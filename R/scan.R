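# Batch interaction scans with multiplicity control and diagnostics
# (PheWAS / labWAS / PWAS / dosage-marker style).

#' Settings for a marker-by-season interaction scan
#'
#' @param covariates character vector naming adjustment covariate columns
#'   in the cohort table.
#' @param mutual_adjust logical; enter all scanned markers as main-effect
#'   co-adjustments in every model (the blood-cell-panel mode).
#' @param threshold_policy \code{"bonferroni"} — Bonferroni over
#'   \code{3 x (number of markers)} tests at level \code{alpha} — or
#'   \code{"fixed"} — compare raw P-values to \code{fixed_threshold}
#'   (the labWAS/PWAS convention, e.g. 0.05/379 = ~1e-4 or
#'   0.05/2923 = ~1.5e-5).
#' @param alpha family-wise level for the Bonferroni policy.
#' @param fixed_threshold raw P-value threshold for the fixed policy.
#' @param reference_amplitude optional positive reference amplitude (SD
#'   units) for the percent scale; default: each model's own baseline
#'   amplitude. The published convention divides by the maximal overall
#'   amplitude (0.091 SD).
#' @param marker_pcs number of principal components of the standardized
#'   marker matrix to append as covariates (the proteomics convention
#'   uses 3); 0 disables.
#' @param method amplitude/acrophase change definition, see
#'   [summarize_interaction()].
#' @param robust logical; HC1 covariance.
#' @return a \code{scan_settings} list.
#' @export
scan_settings <- function(covariates = character(),
                          mutual_adjust = FALSE,
                          threshold_policy = c("bonferroni", "fixed"),
                          alpha = 0.05,
                          fixed_threshold = NULL,
                          reference_amplitude = NULL,
                          marker_pcs = 0,
                          method = "exact",
                          robust = FALSE) {
  threshold_policy <- match.arg(threshold_policy)
  if (threshold_policy == "fixed" && is.null(fixed_threshold))
    stop("fixed threshold policy requires fixed_threshold")
  structure(list(covariates = covariates, mutual_adjust = mutual_adjust,
                 threshold_policy = threshold_policy, alpha = alpha,
                 fixed_threshold = fixed_threshold,
                 reference_amplitude = reference_amplitude,
                 marker_pcs = as.integer(marker_pcs), method = method,
                 robust = robust),
            class = "scan_settings")
}

#' Run a marker-by-season interaction scan over a marker table
#'
#' Fits one interaction model per marker column and summarizes the
#' amplitude, acrophase and displacement changes. Multiplicity control
#' follows the settings' threshold policy; under Bonferroni the family
#' is 3 tests (three characteristics) per marker, so 640 diseases give
#' 1,920 tests. Rows are sorted by the smallest of the three raw
#' P-values. Deterministic given inputs.
#'
#' @param cohort data.frame with \code{outcome}, \code{month} and the
#'   adjustment covariate columns.
#' @param markers data.frame of marker columns, one row per individual
#'   (NA allowed; rows dropped per marker).
#' @param settings a [scan_settings()].
#' @return object of class \code{scan_result}: data.frame with one row
#'   per marker and columns \code{marker}, then estimate/se/z/p for each
#'   of the three characteristics (\code{amp_*} on the percent scale,
#'   \code{acro_*} in months, \code{disp_*} in outcome SD),
#'   \code{p_min}, \code{p_adjusted}, \code{significant}, \code{n_used};
#'   attributes \code{n_tests}, \code{settings}, plus \code{degenerate}
#'   marker names skipped with a warning.
#' @export
run_scan <- function(cohort, markers, settings = scan_settings()) {
  stopifnot(inherits(settings, "scan_settings"),
            all(c("outcome", "month") %in% names(cohort)))
  markers <- as.data.frame(markers)
  if (ncol(markers) == 0) stop("empty marker table")
  m <- ncol(markers)
  covs <- if (length(settings$covariates)) {
    missing_cols <- setdiff(settings$covariates, names(cohort))
    if (length(missing_cols))
      stop("adjustment covariate(s) absent from cohort: ",
           paste(missing_cols, collapse = ", "))
    cohort[settings$covariates]
  } else NULL
  if (settings$marker_pcs > 0) {
    pcs <- marker_principal_components(markers, settings$marker_pcs)
    covs <- if (is.null(covs)) pcs else cbind(covs, pcs)
  }
  rows <- vector("list", m)
  degenerate <- character(0)
  for (j in seq_len(m)) {
    name <- names(markers)[j]
    mutual <- if (settings$mutual_adjust && m > 1) {
      markers[, -j, drop = FALSE]
    } else NULL
    res <- tryCatch({
      fit <- fit_interaction(cohort$outcome, cohort$month, markers[[j]],
                             covariates = covs, mutual_adjust = mutual,
                             robust = settings$robust)
      smry <- summarize_interaction(
        fit, reference_amplitude = settings$reference_amplitude,
        method = settings$method)
      df <- as.data.frame(smry)
      data.frame(
        marker = name,
        amp_estimate = attr(smry, "delta_amplitude_pct"),
        amp_se = attr(smry, "delta_amplitude_pct_se"),
        amp_z = df["amplitude", "t_score"],
        amp_p = df["amplitude", "p_value"],
        acro_estimate = df["acrophase", "estimate"],
        acro_se = df["acrophase", "se"],
        acro_z = df["acrophase", "t_score"],
        acro_p = df["acrophase", "p_value"],
        disp_estimate = df["displacement", "estimate"],
        disp_se = df["displacement", "se"],
        disp_z = df["displacement", "t_score"],
        disp_p = df["displacement", "p_value"],
        n_used = fit$n_used,
        stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      degenerate <- c(degenerate, name)
      rows[j] <- list(NULL)
    } else rows[[j]] <- res
  }
  if (length(degenerate))
    warning("skipped degenerate marker(s): ", paste(degenerate, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop("no marker could be fitted")
  n_tests <- 3L * m
  out$p_min <- pmin(out$amp_p, out$acro_p, out$disp_p)
  if (settings$threshold_policy == "bonferroni") {
    out$p_adjusted <- pmin(1, out$p_min * n_tests)
    out$significant <- out$p_adjusted < settings$alpha
  } else {
    out$p_adjusted <- out$p_min  # fixed policy compares raw P to the threshold
    out$significant <- out$p_min < settings$fixed_threshold
  }
  out <- out[order(out$p_min), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tests = n_tests, settings = settings,
            degenerate = degenerate,
            class = c("scan_result", "data.frame"))
}

# First k principal components of the standardized marker matrix;
# missing entries mean-imputed for the decomposition only.
#' @keywords internal
#' @noRd
marker_principal_components <- function(markers, k) {
  M <- as.matrix(markers)
  for (j in seq_len(ncol(M))) {
    miss <- is.na(M[, j])
    if (all(miss)) stop("marker ", colnames(M)[j], " entirely missing")
    if (any(miss)) M[miss, j] <- mean(M[!miss, j])
  }
  sds <- apply(M, 2, stats::sd)
  M <- scale(M[, sds > 0, drop = FALSE])
  k <- min(k, ncol(M), nrow(M) - 1)
  pc <- stats::prcomp(M, center = FALSE, scale. = FALSE)$x[, seq_len(k), drop = FALSE]
  colnames(pc) <- paste0("marker_PC", seq_len(k))
  as.data.frame(pc)
}

#' Mortality-by-season interaction
#'
#' Convenience wrapper: fits the interaction model with all-cause death
#' (1 = died during follow-up, 0 = censored) as the marker, adjusted for
#' the supplied covariates plus — when present in the cohort — the
#' survival additions: frailty index, length of follow-up, hematocrit,
#' lymphocyte and neutrophil count.
#'
#' @param cohort data.frame with \code{outcome}, \code{month},
#'   \code{death}, \code{follow_up} and covariate columns.
#' @param covariates character vector of baseline adjustment columns.
#' @param reference_amplitude optional percent-scale reference.
#' @param method change definition, see [summarize_interaction()].
#' @return an [summarize_interaction()] result.
#' @export
mortality_interaction <- function(cohort, covariates = character(),
                                  reference_amplitude = NULL,
                                  method = "exact") {
  stopifnot(all(c("outcome", "month", "death") %in% names(cohort)))
  extra <- intersect(c("frailty", "follow_up", "hematocrit",
                       "lymphocytes", "neutrophils"), names(cohort))
  adj <- union(covariates, extra)
  covs <- if (length(adj)) cohort[adj] else NULL
  fit <- fit_interaction(cohort$outcome, cohort$month, cohort$death,
                         covariates = covs)
  summarize_interaction(fit, reference_amplitude = reference_amplitude,
                        method = method)
}

#' Correlations between the z-score streams of a scan
#'
#' Pearson correlations between the amplitude, acrophase and displacement
#' z-score columns across markers; the published scans report, e.g., a
#' negative amplitude-acrophase correlation.
#'
#' @param scan a \code{scan_result} (or data.frame with \code{amp_z},
#'   \code{acro_z}, \code{disp_z}), at least 3 rows.
#' @return 3x3 correlation matrix (amplitude, acrophase, displacement);
#'   entries involving a zero-variance column are \code{NA} with a
#'   warning.
#' @export
zscore_correlations <- function(scan) {
  need <- c("amp_z", "acro_z", "disp_z")
  stopifnot(all(need %in% names(scan)))
  if (nrow(scan) < 3) stop("need at least 3 markers")
  Z <- as.matrix(scan[need])
  colnames(Z) <- c("amplitude", "acrophase", "displacement")
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0)) warning("zero-variance z-score column(s): ",
                             paste(colnames(Z)[sds == 0], collapse = ", "))
  suppressWarnings(stats::cor(Z))
}
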
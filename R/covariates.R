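# Covariate derivation: lifestyle codings, eGFR, frailty index, omics
# pre-processing.

#' Estimated glomerular filtration rate (CKD-EPI 2009 creatinine equation)
#'
#' Serum creatinine in umol/L is converted to mg/dL (divide by 88.42) and
#' passed through the 2009 CKD-EPI creatinine equation with sex-specific
#' constants: females kappa = 0.7, alpha = -0.329, scale 144; males
#' kappa = 0.9, alpha = -0.411, scale 141; both use exponent -1.209 above
#' kappa and the common age factor 0.993^age. The race coefficient is
#' fixed at 1 (European-ancestry analysis set).
#'
#' @param creatinine_umol positive serum creatinine, umol/L (vectorized).
#' @param age age in years.
#' @param sex character/factor, \code{"female"} or \code{"male"}.
#' @return eGFR in mL/min/1.73m^2.
#' @examples
#' egfr_ckd_epi(61.894, 50, "female")  # 144 * 0.993^50 ~ 101.4
#' @export
egfr_ckd_epi <- function(creatinine_umol, age, sex) {
  if (any(!is.finite(creatinine_umol)) || any(creatinine_umol <= 0))
    stop("creatinine must be positive")
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be positive")
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("female", "male")))
    stop('sex must be "female" or "male"')
  cr <- creatinine_umol / 88.42
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.329, -0.411)
  scale <- ifelse(sex == "female", 144, 141)
  scale * pmin(cr / kappa, 1)^alpha * pmax(cr / kappa, 1)^-1.209 * 0.993^age
}

#' Frailty index as percent of self-reported ailments
#'
#' @param ailment_flags logical/0-1 vector of one individual's answers, or
#'   a matrix/data.frame with one row per individual; \code{NA} counts as
#'   not reported.
#' @param n_items total number of queried items Q; defaults to the number
#'   of columns (matrix input) or the vector length.
#' @return percentage(s) in [0, 100].
#' @export
frailty_index <- function(ailment_flags, n_items = NULL) {
  if (is.data.frame(ailment_flags)) ailment_flags <- as.matrix(ailment_flags)
  if (is.matrix(ailment_flags)) {
    q <- n_items %||% ncol(ailment_flags)
    if (q <= 0) stop("n_items must be positive")
    return(100 * rowSums(ailment_flags == 1 | ailment_flags == TRUE,
                         na.rm = TRUE) / q)
  }
  q <- n_items %||% length(ailment_flags)
  if (q <= 0) stop("n_items must be positive")
  100 * sum(ailment_flags == 1 | ailment_flags == TRUE, na.rm = TRUE) / q
}

#' Derive lifestyle and clinical adjustment covariates
#'
#' Applies the fixed coding rules used throughout the analyses, in which
#' missingness always falls into the reference category of a binary
#' exposure:
#' \itemize{
#'   \item \code{ever_smoked}: ever smoked (past/current) vs never or missing;
#'   \item \code{risky_alcohol}: more than three drinks a week vs less or missing;
#'   \item \code{low_activity}: below the activity recommendation vs meets it or missing;
#'   \item \code{university_degree}: degree vs none or missing;
#'   \item \code{packyears}: 0 for never-smokers (including missing status);
#'     otherwise group-median imputation within past and current smokers;
#'   \item \code{bmi}: median-imputed;
#'   \item \code{egfr}: CKD-EPI from creatinine/age/sex, then median-imputed.
#' }
#' Medians are computed from the non-missing values of the input sample.
#' The function is idempotent: applying it to its own output changes
#' nothing.
#'
#' @param raw data.frame with (any of) columns \code{bmi},
#'   \code{smoking_status} ("never"/"past"/"current", NA allowed),
#'   \code{packyears}, \code{drinks_per_week}, \code{meets_activity}
#'   (0/1), \code{university} (0/1), \code{creatinine_umol}, \code{age},
#'   \code{sex}.
#' @return the input data.frame with derived columns added/replaced.
#' @export
derive_lifestyle <- function(raw) {
  stopifnot(is.data.frame(raw))
  out <- raw
  if ("smoking_status" %in% names(out)) {
    st <- tolower(as.character(out$smoking_status))
    st[is.na(st)] <- "missing"
    out$ever_smoked <- as.integer(st %in% c("past", "current"))
    if ("packyears" %in% names(out)) {
      py <- out$packyears
      py[st %in% c("never", "missing")] <- 0
      for (grp in c("past", "current")) {
        idx <- st == grp
        if (any(idx & is.na(py))) {
          med <- stats::median(py[idx], na.rm = TRUE)
          if (is.na(med)) med <- 0  # whole group missing
          py[idx & is.na(py)] <- med
        }
      }
      out$packyears <- py
    }
  }
  if ("drinks_per_week" %in% names(out))
    out$risky_alcohol <- as.integer(!is.na(out$drinks_per_week) &
                                      out$drinks_per_week > 3)
  if ("meets_activity" %in% names(out))
    out$low_activity <- as.integer(!is.na(out$meets_activity) &
                                     out$meets_activity == 0)
  if ("university" %in% names(out))
    out$university_degree <- as.integer(!is.na(out$university) &
                                          out$university == 1)
  if ("bmi" %in% names(out) && anyNA(out$bmi))
    out$bmi[is.na(out$bmi)] <- stats::median(out$bmi, na.rm = TRUE)
  if (all(c("creatinine_umol", "age", "sex") %in% names(out))) {
    ok <- !is.na(out$creatinine_umol)
    egfr <- rep(NA_real_, nrow(out))
    egfr[ok] <- egfr_ckd_epi(out$creatinine_umol[ok], out$age[ok], out$sex[ok])
    if (anyNA(egfr)) egfr[is.na(egfr)] <- stats::median(egfr, na.rm = TRUE)
    out$egfr <- egfr
  }
  out
}

#' Log2-transform and standardize an omics marker matrix
#'
#' Per marker (column): impute missing entries, log2-transform, then
#' center and scale to mean 0 / SD 1 — the pre-processing applied to
#' NMR-metabolomics-style panels before association testing. Default
#' imputation is the per-marker mean of the observed (positive) values;
#' \code{impute = "lowrank"} uses an iterative truncated-SVD imputer that
#' exploits between-marker collinearity (an approximation to PCA-based
#' imputation).
#'
#' @param mat numeric matrix or data.frame, samples x markers; entries
#'   must be positive where present.
#' @param impute \code{"mean"} or \code{"lowrank"}.
#' @param rank rank of the low-rank imputer.
#' @param max_iter,tol iteration controls for the low-rank imputer.
#' @return numeric matrix of the same dimension, each column mean 0, SD 1.
#' @export
log2_standardize_omics <- function(mat, impute = c("mean", "lowrank"),
                                   rank = 3, max_iter = 50, tol = 1e-6) {
  impute <- match.arg(impute)
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) colnames(mat) <- paste0("marker", seq_len(ncol(mat)))
  nonpos <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(nonpos))
    stop("non-positive value in marker ", colnames(mat)[nonpos[1, 2]],
         " (row ", nonpos[1, 1], "); log2 transform requires positive values")
  if (impute == "mean") {
    for (j in seq_len(ncol(mat))) {
      miss <- is.na(mat[, j])
      if (all(miss)) stop("marker ", colnames(mat)[j], " is entirely missing")
      if (any(miss)) mat[miss, j] <- mean(mat[!miss, j])
    }
    lg <- log2(mat)
  } else {
    lg <- log2(mat)  # impute on the log scale, where markers are closer to linear
    miss <- is.na(lg)
    mu <- colMeans(lg, na.rm = TRUE)
    if (anyNA(mu)) stop("a marker is entirely missing")
    filled <- lg
    filled[miss] <- matrix(mu, nrow(lg), ncol(lg), byrow = TRUE)[miss]
    k <- min(rank, dim(lg) - 1)
    prev <- filled[miss]
    for (it in seq_len(max_iter)) {
      ctr <- colMeans(filled)
      sv <- svd(sweep(filled, 2, ctr), nu = k, nv = k)
      approx <- sv$u %*% (diag(sv$d[seq_len(k)], k) %*% t(sv$v))
      approx <- sweep(approx, 2, ctr, `+`)
      filled[miss] <- approx[miss]
      if (length(prev) == 0 ||
          max(abs(filled[miss] - prev)) < tol * (1 + max(abs(prev)))) break
      prev <- filled[miss]
    }
    lg <- filled
  }
  sds <- apply(lg, 2, stats::sd)
  if (any(sds == 0))
    stop("zero variance in marker ",
         colnames(lg)[which(sds == 0)[1]], " after transform")
  scale(lg, center = TRUE, scale = sds)[, , drop = FALSE]
}
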
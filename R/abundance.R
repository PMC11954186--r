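# mtDNA abundance quantification from coverage summaries: ratio, QC,
# standardization.

#' Normalized mtDNA abundance ratio
#'
#' Relative mitochondrial DNA content is proxied by the mean fold-coverage
#' of the mitochondrial genome from off-target sequencing reads, divided
#' by the total number of reads mapped to the genome. The ratio is
#' invariant to proportional rescaling of both quantities.
#'
#' @param mt_mean_coverage non-negative mean coverage (X) of the
#'   mitochondrial contig.
#' @param total_mapped_reads positive total mapped read count.
#' @return the abundance ratio (vectorized).
#' @examples
#' normalized_mtdna_ratio(0.66, 4e7)  # 1.65e-08
#' @export
normalized_mtdna_ratio <- function(mt_mean_coverage, total_mapped_reads) {
  if (any(!is.finite(total_mapped_reads)) || any(total_mapped_reads <= 0))
    stop("total_mapped_reads must be positive")
  if (any(!is.finite(mt_mean_coverage)) || any(mt_mean_coverage < 0))
    stop("mt_mean_coverage must be non-negative")
  mt_mean_coverage / total_mapped_reads
}

#' Interquartile-range outlier filter
#'
#' Keeps value \eqn{v} iff \eqn{|v - median| \le k \cdot IQR}, computed in
#' a single pass over the full input (the median and IQR are not
#' recomputed after exclusions). Default \code{k = 4}. Quartiles use
#' linear interpolation between order statistics (R quantile type 7).
#'
#' With a degenerate spread (IQR = 0) the rule is applied literally: only
#' values equal to the median are kept, and a warning is emitted.
#'
#' @param values numeric vector (at least 4 finite values).
#' @param k positive IQR multiplier, default 4.
#' @return logical mask aligned with the input; \code{TRUE} = keep.
#' @export
iqr_outlier_mask <- function(values, k = 4) {
  stopifnot(is.numeric(values), k > 0)
  finite <- is.finite(values)
  if (sum(finite) < 4) stop("need at least 4 finite values")
  med <- stats::median(values[finite])
  iqr <- stats::IQR(values[finite], type = 7)
  if (iqr == 0) {
    warning("IQR is zero; keeping only values equal to the median")
    return(finite & values == med)
  }
  finite & abs(values - med) <= k * iqr
}

#' Standardize a numeric vector to mean 0, sample SD 1
#'
#' @param values numeric vector, length >= 2, nonzero variance.
#' @return standardized vector, order preserved.
#' @export
standardize <- function(values) {
  stopifnot(is.numeric(values))
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("need at least 2 finite values")
  s <- stats::sd(values[ok])
  if (s == 0) stop("zero variance: cannot standardize")
  (values - mean(values[ok])) / s
}

#' mtDNA abundance pipeline: ratio, QC filter, standardization
#'
#' Computes the normalized abundance ratio per sample, applies the
#' k-times-IQR-from-the-median exclusion in a single pass, and
#' standardizes the surviving values to mean 0 / SD 1. Standardization is
#' deliberately performed after exclusion so the SD scale refers to the
#' QC-passed analysis set; excluded samples get \code{NA} z-values.
#'
#' @param coverage data.frame with columns \code{sample_id},
#'   \code{mt_mean_coverage}, \code{total_mapped_reads} (e.g. from
#'   [read_coverage_summaries()]).
#' @param iqr_multiplier positive IQR multiplier for the QC filter.
#' @return data.frame with columns \code{sample_id}, \code{ratio},
#'   \code{qc_pass}, \code{z_value}; attribute \code{excluded_fraction}.
#' @export
mtdna_abundance <- function(coverage, iqr_multiplier = 4) {
  req <- c("sample_id", "mt_mean_coverage", "total_mapped_reads")
  missing_cols <- setdiff(req, names(coverage))
  if (length(missing_cols))
    stop("coverage table lacks column(s): ", paste(missing_cols, collapse = ", "))
  ratio <- normalized_mtdna_ratio(coverage$mt_mean_coverage,
                                  coverage$total_mapped_reads)
  keep <- iqr_outlier_mask(ratio, k = iqr_multiplier)
  z <- rep(NA_real_, length(ratio))
  z[keep] <- standardize(ratio[keep])
  out <- data.frame(sample_id = coverage$sample_id, ratio = ratio,
                    qc_pass = keep, z_value = z,
                    stringsAsFactors = FALSE)
  attr(out, "excluded_fraction") <- mean(!keep)
  out
}
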
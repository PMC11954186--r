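# File readers/writers and configuration. All delimited output is
# tab-separated UTF-8 with '.' decimals and NA for missing; every file
# carries '#'-prefixed metadata lines (seed, package version, config
# hash) sufficient to reproduce it.

meta_header <- function(meta = list()) {
  meta <- c(list(package = paste0("mtcosinor ",
                                  as.character(utils::packageVersion("mtcosinor"))),
                 created = "deterministic"), meta)
  paste0("# ", names(meta), "=", vapply(meta, as.character, character(1)))
}

#' Write a delimited table with a metadata header
#'
#' @param x data.frame.
#' @param path output path.
#' @param meta named list recorded as \code{# key=value} comment lines.
#' @export
write_table_meta <- function(x, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a cohort table from delimited text
#'
#' Reads a tab-delimited phenotype table ('#' lines are metadata),
#' optionally renaming columns via \code{mapping} (names = canonical,
#' values = file column names), and validates the month column.
#'
#' @param path file path.
#' @param mapping optional named character vector, e.g.
#'   \code{c(month = "recruitment_month")}.
#' @return data.frame with validated \code{month}.
#' @export
read_cohort_table <- function(path, mapping = NULL) {
  x <- utils::read.delim(path, comment.char = "#", sep = "\t",
                         stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    absent <- setdiff(unname(mapping), names(x))
    if (length(absent))
      stop("mapped column(s) absent from ", path, ": ",
           paste(absent, collapse = ", "))
    names(x)[match(unname(mapping), names(x))] <- names(mapping)
  }
  if (!"month" %in% names(x)) stop("cohort table lacks a 'month' column")
  bad <- which(is.na(x$month) | !(x$month %in% 1:12))
  if (length(bad))
    stop("month out of range 1..12 in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  x$month <- as.integer(x$month)
  x
}

#' Write a cohort table
#' @param cohort data.frame.
#' @param path output path.
#' @param meta metadata list, see [write_table_meta()].
#' @export
write_cohort_table <- function(cohort, path, meta = list()) {
  write_table_meta(cohort, path, meta)
}

#' Read one mosdepth-style coverage summary
#'
#' Parses the whitespace/tab-delimited summary dialect (columns
#' \code{chrom}, \code{length}, \code{bases}, \code{mean}) and returns
#' the mean coverage of the mitochondrial contig, accepted as
#' \code{"MT"} or \code{"chrM"}.
#'
#' @param path summary file path.
#' @return mitochondrial mean coverage (scalar).
#' @export
read_mosdepth_summary <- function(path) {
  x <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         comment.char = "#")
  need <- c("chrom", "length", "bases", "mean")
  if (!all(need %in% names(x)))
    stop("not a mosdepth summary (need columns chrom/length/bases/mean): ", path)
  row <- x[x$chrom %in% c("MT", "chrM"), , drop = FALSE]
  if (nrow(row) == 0)
    stop("no mitochondrial contig (MT or chrM) in ", path)
  as.numeric(row$mean[1])
}

#' Write per-sample coverage summaries and a reads manifest
#'
#' One mosdepth-dialect summary file per sample
#' (\code{<sample_id>.mosdepth.summary.txt}) plus a two-column
#' tab-delimited manifest (\code{sample_id}, \code{total_mapped_reads}).
#'
#' @param coverage data.frame from [generate_coverage()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_coverage_summaries <- function(coverage, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(coverage))) {
    f <- file.path(dir, paste0(coverage$sample_id[i], ".mosdepth.summary.txt"))
    utils::write.table(
      data.frame(chrom = coverage$chrom[i], length = coverage$length[i],
                 bases = coverage$bases[i],
                 mean = sprintf("%.6g", coverage$mt_mean_coverage[i])),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- file.path(dir, "reads_manifest.tsv")
  utils::write.table(coverage[c("sample_id", "total_mapped_reads")],
                     manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a directory of coverage summaries plus the reads manifest
#'
#' @param dir directory containing \code{*.mosdepth.summary.txt} files.
#' @param manifest path to the reads manifest; defaults to
#'   \code{reads_manifest.tsv} inside \code{dir}.
#' @return data.frame with \code{sample_id}, \code{mt_mean_coverage},
#'   \code{total_mapped_reads}.
#' @export
read_coverage_summaries <- function(dir, manifest = file.path(dir, "reads_manifest.tsv")) {
  files <- list.files(dir, pattern = "\\.mosdepth\\.summary\\.txt$",
                      full.names = TRUE)
  if (!length(files)) stop("no *.mosdepth.summary.txt files in ", dir)
  ids <- sub("\\.mosdepth\\.summary\\.txt$", "", basename(files))
  cov <- vapply(files, read_mosdepth_summary, numeric(1))
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "total_mapped_reads") %in% names(man)))
    stop("reads manifest needs columns sample_id, total_mapped_reads")
  idx <- match(ids, man$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from reads manifest: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  data.frame(sample_id = ids, mt_mean_coverage = unname(cov),
             total_mapped_reads = man$total_mapped_reads[idx],
             stringsAsFactors = FALSE)
}

#' Write scan results as delimited text with metadata
#'
#' Fixed column order (marker, estimate/se/z/p for amplitude, acrophase,
#' displacement, p_min, p_adjusted, significant, n_used); metadata
#' header records the seed, number of tests and a settings hash so the
#' file is reproducible byte-for-byte.
#'
#' @param scan a \code{scan_result}.
#' @param path output path.
#' @param seed seed recorded in the metadata.
#' @export
write_scan_results <- function(scan, path, seed = NA) {
  stopifnot(inherits(scan, "scan_result"))
  settings <- attr(scan, "settings")
  hash <- sum(utf8ToInt(paste(deparse(unclass(settings)), collapse = ""))) %% 1e9
  df <- as.data.frame(scan)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  write_table_meta(df, path,
                   meta = list(seed = seed,
                               n_tests = attr(scan, "n_tests"),
                               threshold_policy = settings$threshold_policy,
                               settings_hash = hash))
}

#' Read back scan results written by [write_scan_results()]
#' @param path file path.
#' @return data.frame (numeric columns restored).
#' @export
read_scan_results <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  x$significant <- as.logical(x$significant)
  x
}

#' Write a truth record as JSON
#' @param truth truth list from [generate_cohort()].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' The format is chosen by extension: \code{.yaml}/\code{.yml} or
#' \code{.json}. Typical keys: input paths, column mapping, adjustment
#' sets (named lists of covariate columns), QC settings
#' (\code{iqr_multiplier}), scan settings, \code{reference_amplitude},
#' \code{seed}.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json: ", path)
}
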
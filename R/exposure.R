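#' Read an aggregated exposure table
#'
#' Reads a CSV of aggregated urinary-biomarker survey summaries: one row per
#' study, population group and biomarker, holding percentiles of the
#' concentration distribution in ug/L (not creatinine-adjusted) and optional
#' 95% confidence bounds on the 95th percentile. Cells that could not be
#' estimated (typically because of low detection frequency) are marked `NR`
#' or left empty; they become missing values, never zero, and rows with a
#' missing 95th percentile are later excluded from ratio computations rather
#' than silently treated as unexposed.
#'
#' Validation is row-level: percentiles must be non-negative and
#' non-decreasing in percentile order (`p05 <= p50 <= p95`), and confidence
#' bounds must bracket the point estimate. Violations abort citing the row.
#'
#' @param path CSV with columns
#'   `study_id,country,population,biomarker,n,p05,p50,p95,p95_lcl,p95_ucl,note`.
#' @return A tibble with numeric percentile columns (`NA` where not
#'   reported).
#' @seealso [default_exposure()] for the packaged survey table.
#' @export
read_exposure_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Exposure file not found: %s", path),
          class = "hbmtier_load_error")
  }
  required <- c("study_id", "country", "population", "biomarker", "n",
                "p05", "p50", "p95", "p95_lcl", "p95_ucl", "note")
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "hbmtier_load_error")
  }
  num_cols <- c("n", "p05", "p50", "p95", "p95_lcl", "p95_ucl")
  for (col in num_cols) {
    raw <- x[[col]]
    val <- suppressWarnings(as.numeric(ifelse(raw %in% c("NR", "", NA), NA, raw)))
    bad <- which(!is.na(raw) & !raw %in% c("NR", "") & is.na(val))
    if (length(bad)) {
      abort(sprintf("%s: unparseable `%s` in row(s) %s", path, col,
                    paste(bad, collapse = ", ")),
            class = "hbmtier_validation_error")
    }
    x[[col]] <- val
  }
  neg <- which(apply(x[, c("p05", "p50", "p95")] < 0, 1, any, na.rm = TRUE))
  if (length(neg)) {
    abort(sprintf("%s: negative concentration in row(s) %s", path,
                  paste(neg, collapse = ", ")),
          class = "hbmtier_validation_error")
  }
  non_mono <- which((!is.na(x$p05) & !is.na(x$p50) & x$p05 > x$p50) |
                    (!is.na(x$p50) & !is.na(x$p95) & x$p50 > x$p95) |
                    (!is.na(x$p05) & !is.na(x$p95) & x$p05 > x$p95))
  if (length(non_mono)) {
    abort(sprintf("%s: percentiles not non-decreasing in row(s) %s", path,
                  paste(non_mono, collapse = ", ")),
          class = "hbmtier_validation_error")
  }
  bad_ci <- which((!is.na(x$p95_lcl) & !is.na(x$p95) & x$p95_lcl > x$p95) |
                  (!is.na(x$p95_ucl) & !is.na(x$p95) & x$p95_ucl < x$p95))
  if (length(bad_ci)) {
    abort(sprintf("%s: confidence bounds do not bracket p95 in row(s) %s",
                  path, paste(bad_ci, collapse = ", ")),
          class = "hbmtier_validation_error")
  }
  as_tibble(x)
}

#' Write an aggregated exposure table
#'
#' Inverse of [read_exposure_table()]; missing values are written as `NR` so
#' a write-read round trip preserves the missing-value markers.
#'
#' @param exposure Tibble in the exposure schema.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_exposure_table <- function(exposure, path) {
  readr::write_csv(exposure, path, na = "NR")
  invisible(path)
}

#' Packaged exposure summaries from the aligned studies
#'
#' The 95th percentiles of urinary pyrethroid biomarkers for six children
#' studies (Belgium, Cyprus, France, Israel, Slovenia, The Netherlands) and
#' four adult studies (France, Germany, Israel, Switzerland), 2014-2021.
#' Values printed in the source assessment are transcribed verbatim; values
#' only recoverable from the published risk-ratio table are back-calculated
#' (ratio times guidance value) and flagged as such in the `note` column.
#' Percentiles that could not be estimated are `NA`.
#'
#' @return A tibble in the [read_exposure_table()] schema.
#' @export
default_exposure <- function() {
  read_exposure_table(system.file("extdata", "exposure_hbm4eu.csv",
                                  package = "hbmtier", mustWork = TRUE))
}

#' Summary for a sum biomarker
#'
#' Screening against the combined marker (e.g. the sum of 3-PBA and 4-FPBA)
#' requires a percentile of the within-individual sum. Percentiles are not
#' additive, so two marginal summaries cannot be combined after aggregation:
#' this operation passes a *reported* sum summary through (validating that it
#' belongs to the same study and population as the components) and refuses
#' when only marginal summaries are available.
#'
#' @param a,b One-row exposure tibbles for the component biomarkers.
#' @param reported Optional one-row exposure tibble holding the sum as
#'   reported by the study.
#' @return A one-row tibble tagged with the combined biomarker id.
#' @export
sum_biomarker_summary <- function(a, b, reported = NULL) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (a$study_id != b$study_id || a$population != b$population) {
    abort("Component summaries must come from the same study and population.",
          class = "hbmtier_validation_error")
  }
  if (is.null(reported)) {
    abort(paste("Cannot add percentile summaries: a percentile of a sum is",
                "not the sum of percentiles. Supply the study-reported sum",
                "via `reported`."),
          class = "hbmtier_refusal_error")
  }
  stopifnot(nrow(reported) == 1)
  if (reported$study_id != a$study_id || reported$population != a$population) {
    abort("Reported sum must come from the same study and population.",
          class = "hbmtier_validation_error")
  }
  out <- reported
  out$biomarker <- paste(a$biomarker, b$biomarker, sep = "+")
  out
}
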
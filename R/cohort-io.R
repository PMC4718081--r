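#' Read a cohort CSV
#'
#' Reads subject-by-visit records from the documented CSV layout (header
#' `subject_id, group, month, abeta, tau, ptau, mmse, age, sex`; markers in
#' pg/mL).  Rows with a missing marker or MMSE value are excluded and counted,
#' mirroring the exclusion of subjects with incomplete data in longitudinal
#' CSF studies.
#'
#' @param path CSV file path.
#' @return Cohort tibble; the number of excluded rows is attached as attribute
#'   `n_excluded` and reported via a message.
#' @export
read_cohort <- function(path) {
  required <- c("subject_id", "group", "month", "abeta", "tau", "ptau",
                "mmse", "age", "sex")
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort CSV is missing required columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "minibalance_parse_error")
  }
  complete <- complete.cases(tbl[, c(marker_names(), "mmse")])
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("excluded %d row(s) with missing marker or MMSE values",
                    n_excluded))
  }
  tbl <- tbl[complete, , drop = FALSE]
  tbl$group <- factor(tbl$group, levels = c("Normal", "MCI", "AD"))
  if (anyNA(tbl$group)) {
    abort("`group` must be one of Normal, MCI, AD",
          class = "minibalance_parse_error")
  }
  tbl$mmse <- as.integer(tbl$mmse)
  attr(tbl, "n_excluded") <- n_excluded
  tbl
}

#' Write a cohort CSV
#'
#' Writes the documented analysis-facing columns only; generator ground-truth
#' columns such as `latent_severity` are dropped.
#'
#' @param data Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  cols <- c("subject_id", "group", "month", "abeta", "tau", "ptau",
            "mmse", "age", "sex")
  readr::write_csv(data[, intersect(cols, names(data))], path)
  invisible(path)
}
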
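#' Cohort file dialect
#'
#' Cohorts travel as TSV with this fixed column order and header. Logical
#' columns are written as `TRUE`/`FALSE` (`1`/`0` accepted on read), missing
#' values as empty fields (`NA` accepted on read).
#'
#' @return Named character vector: column name -> type
#'   (`"character"`, `"numeric"`, `"logical"`).
#' @export
cohort_columns <- function() {
  c(subject_id = "character", age_baseline = "numeric", sex = "character",
    setNames(rep("numeric", 7), lipid_species()),
    bmi = "numeric", waist = "numeric", tg = "numeric", tc = "numeric",
    hdl = "numeric", ldl = "numeric", crp = "numeric",
    smoking = "logical", diabetes = "logical",
    lipid_lowering_tx = "logical", bp_lowering_tx = "logical",
    sbp = "numeric", dbp = "numeric",
    event_new_onset = "logical", age_at_event_or_censor = "numeric",
    died = "logical")
}

#' Write a cohort to TSV
#'
#' @param cohort Cohort tibble with the [cohort_columns()] columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- names(cohort_columns())
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0) {
    abort_cfg(paste0("cohort lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  readr::write_tsv(cohort[, cols], path, na = "")
  invisible(path)
}

#' Read a cohort from TSV (or any delimited file with a column map)
#'
#' Columns are read untyped and converted with row-level error reporting; a
#' malformed value (e.g. a non-numeric lipid) either aborts with its line
#' number (`on_error = "error"`) or drops the row with a logged count
#' (`on_error = "skip"`).
#'
#' @param path Input file.
#' @param column_map Optional named character vector mapping canonical column
#'   names (see [cohort_columns()]) to the file's column names.
#' @param on_error `"error"` (default) or `"skip"` for malformed rows.
#' @param delim Field delimiter, default tab.
#' @return Cohort tibble; attribute `n_skipped` counts dropped rows.
#' @export
read_cohort <- function(path, column_map = NULL,
                        on_error = c("error", "skip"), delim = "\t") {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) abort_cfg(paste0("cohort file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           col_types = readr::cols(.default = readr::col_character()),
                           show_col_types = FALSE, progress = FALSE)
  spec <- cohort_columns()
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      file_col <- column_map[[canon]]
      if (!file_col %in% names(raw)) {
        abort_cfg(sprintf("mapped column '%s' (for '%s') not present in %s",
                          file_col, canon, path))
      }
      names(raw)[names(raw) == file_col] <- canon
    }
  }
  missing_cols <- setdiff(names(spec), names(raw))
  if (length(missing_cols) > 0) {
    abort_cfg(paste0("cohort file lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[, names(spec)]

  bad_rows <- integer(0)
  out <- raw
  for (col in names(spec)) {
    x <- raw[[col]]
    if (spec[[col]] == "numeric") {
      conv <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & is.na(conv))
    } else if (spec[[col]] == "logical") {
      up <- toupper(trimws(x))
      conv <- dplyr::case_when(up %in% c("TRUE", "T", "1") ~ TRUE,
                               up %in% c("FALSE", "F", "0") ~ FALSE,
                               TRUE ~ NA)
      bad <- which(!is.na(x) & is.na(conv))
    } else {
      conv <- x
      bad <- integer(0)
    }
    if (length(bad) > 0 && on_error == "error") {
      stop(sprintf("malformed value in column '%s' at line %d of %s: '%s'",
                   col, bad[1] + 1L, path, x[bad[1]]), call. = FALSE)
    }
    bad_rows <- union(bad_rows, bad)
    out[[col]] <- conv
  }
  if (length(bad_rows) > 0) {
    message(sprintf("read_cohort: skipped %d malformed row(s) (lines %s)",
                    length(bad_rows),
                    paste(sort(bad_rows) + 1L, collapse = ", ")))
    out <- out[-bad_rows, , drop = FALSE]
  }
  attr(out, "n_skipped") <- length(bad_rows)
  out
}
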
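record_columns <- function() {
  c("id", "age", "sex", "wealth", exposure_column(risk_factors()), "weight")
}

#' Validate a survey record data.frame
#'
#' Checks the documented record schema: `age >= 0`, `weight >= 0`, `wealth`
#' drawn from the wealth vocabulary, and every non-missing exposure value
#' drawn from the exposure vocabulary. Exposure columns may contain `NA`
#' (a respondent can be missing for one factor and present for another);
#' `sex` is optional and filled with `NA` if absent.
#'
#' @param records A data.frame of survey records.
#' @return The validated records, invisibly unchanged apart from an added
#'   all-`NA` `sex` column when missing.
#' @export
validate_records <- function(records) {
  records <- as.data.frame(records)
  if (!"sex" %in% names(records)) records$sex <- NA_character_
  missing_cols <- setdiff(record_columns(), names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(records$age) || anyNA(records$age) ||
      any(records$age < 0)) {
    stop("age must be nonnegative and non-missing for every record",
         call. = FALSE)
  }
  if (!is.numeric(records$weight) || anyNA(records$weight) ||
      any(records$weight < 0)) {
    stop("weight must be nonnegative and non-missing for every record",
         call. = FALSE)
  }
  bad_w <- !records$wealth %in% wealth_levels()
  if (any(bad_w)) {
    i <- which(bad_w)[1L]
    stop("record '", records$id[i], "': wealth label '", records$wealth[i],
         "' is not one of ", paste(wealth_levels(), collapse = ", "),
         call. = FALSE)
  }
  for (f in risk_factors()) {
    col <- exposure_column(f)
    v <- records[[col]]
    bad <- !is.na(v) & !v %in% exposure_levels()
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("record '", records$id[i], "': ", col, " label '", v[i],
           "' is not one of ", paste(exposure_levels(), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(records[, record_columns()])
}

#' Read and write survey records as CSV
#'
#' The CSV dialect is a plain comma-separated file with header
#' `id,age,sex,wealth,exposure_alcohol,exposure_tobacco,exposure_diet,exposure_inactivity,weight`.
#' Empty exposure fields are missing values. `read_records()` fails with
#' per-row diagnostics for unparseable ages or negative weights and with the
#' offending column name when the header is incomplete; a `write_records()`
#' then `read_records()` round trip reproduces all fields exactly.
#'
#' @param path CSV file path.
#' @param records Data.frame of survey records.
#' @return `read_records()` returns the validated record data.frame;
#'   `write_records()` returns `path` invisibly.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(setdiff(record_columns(), "sex"), names(raw))
  if (length(missing_cols) > 0L) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  age <- suppressWarnings(as.numeric(raw$age))
  bad_age <- which(is.na(age) | age < 0)
  if (length(bad_age) > 0L) {
    problems <- c(problems, paste0(
      "row ", bad_age, ": unparseable or negative age '",
      raw$age[bad_age], "'"))
  }
  weight <- suppressWarnings(as.numeric(raw$weight))
  weight[is.na(raw$weight)] <- 1
  bad_wt <- which(is.na(weight) | weight < 0)
  if (length(bad_wt) > 0L) {
    problems <- c(problems, paste0(
      "row ", bad_wt, ": unparseable or negative weight '",
      raw$weight[bad_wt], "'"))
  }
  if (length(problems) > 0L) {
    stop("invalid records in '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  raw$age <- age
  raw$weight <- weight
  validate_records(raw)
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
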
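#' Read and write person-level survey records
#'
#' The canonical tabular format is CSV with an explicit header and columns
#' `area_id`, `sex`, `age_group`, `race_group`, `survey_year`, `outcome`,
#' `weight`.  Rows with a missing outcome (empty, NA) are dropped with a
#' warning reporting the count, mirroring the standard survey practice of
#' excluding missing, refused, or don't-know responses.  Unknown demographic
#' labels and non-positive weights are errors naming the offending row.
#'
#' @param path CSV file path.
#' @param records data.frame of person records.
#' @return `read_person_records` returns a validated data.frame of person
#'   records; `write_person_records` returns `path` invisibly.
#' @export
read_person_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(area_id = "character"))
  needed <- c("area_id", "sex", "age_group", "race_group",
              "survey_year", "outcome", "weight")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  df <- df[, needed]
  n_missing <- sum(is.na(df$outcome))
  if (n_missing > 0) {
    warning(sprintf("dropped %d record(s) with missing outcome", n_missing),
            call. = FALSE)
    df <- df[!is.na(df$outcome), , drop = FALSE]
    rownames(df) <- NULL
  }
  validate_person_records(df)
  df
}

#' @rdname read_person_records
#' @export
write_person_records <- function(records, path) {
  validate_person_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

## structural checks shared by readers and the generator's consumers
validate_person_records <- function(df) {
  stopifnot(is.data.frame(df))
  check_levels(df$age_group, age_groups(), "age_group")
  check_levels(df$race_group, race_groups(), "race_group")
  if (!all(df$outcome %in% c(0L, 1L))) {
    stop(sprintf("outcome must be 0/1 (row %d)",
                 which(!(df$outcome %in% c(0L, 1L)))[1]), call. = FALSE)
  }
  bad_w <- which(!is.finite(df$weight) | df$weight <= 0)
  if (length(bad_w) > 0) {
    stop(sprintf("weight must be positive (row %d)", bad_w[1]), call. = FALSE)
  }
  invisible(TRUE)
}
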
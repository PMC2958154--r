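#' Direct age-standardized survey estimate for one area
#'
#' Computes the direct, weighted, age-standardized prevalence estimate from
#' the records of a single area (and, by convention, a single sex): within
#' each survey year x age group cell, prevalence is the poststratification-
#' weight-weighted mean of the outcome; cell estimates are then averaged
#' over years with equal year weights; finally the age-specific rates are
#' combined using the standard population, with the standard weights
#' renormalized over the age groups actually present in the data.
#'
#' @param records Person records for one area (and sex).
#' @param std A [standard_population()].
#' @return Estimate in [0, 1].
#' @examples
#' recs <- data.frame(area_id = "x", sex = "male", age_group = "50-54",
#'                    race_group = "White", survey_year = 2004,
#'                    outcome = c(1, 0, 1), weight = c(1, 1, 2))
#' direct_estimate(recs, standard_population())  # 0.75
#' @export
direct_estimate <- function(records, std = standard_population()) {
  if (is.null(records) || nrow(records) == 0) {
    stop("direct estimate undefined for zero records", call. = FALSE)
  }
  validate_person_records(records)
  ## year x age cell weighted means
  cell <- paste(records$survey_year, records$age_group, sep = "\r")
  num <- tapply(records$outcome * records$weight, cell, sum)
  den <- tapply(records$weight, cell, sum)
  cell_prev <- num / den
  cell_age <- sub("^[^\r]*\r", "", names(cell_prev))
  ## equal-weight average over years within age group
  age_prev <- tapply(cell_prev, cell_age, mean)
  ## standardize over the age groups present
  w <- std[names(age_prev)]
  sum(w / sum(w) * age_prev)
}

#' Build the gold standard from large-sample areas
#'
#' The gold standard is the set of direct, age-standardized, sex-specific
#' estimates for areas whose sample size exceeds a threshold in *both* of
#' two pooled year windows.  Because no single window is authoritative for
#' the estimate itself, the window used to compute the estimate is a
#' parameter (default: the second window).
#'
#' @param records All person records (may contain several sexes).
#' @param window1,window2 Integer vectors of years defining the two pooling
#'   windows (e.g. `1996:2004` and `2000:2008`).
#' @param threshold Minimum sample size; an area x sex cell qualifies when
#'   its record count is strictly greater than `threshold` in both windows.
#' @param std A [standard_population()].
#' @param estimate_window Years pooled for the estimate (default `window2`).
#' @return data.frame of class `gold_standard` with columns `area_id`,
#'   `sex`, `estimate`, `n_pooled` (records in `estimate_window`), and the
#'   attribute `years` (the estimate window).  Empty result gives a warning,
#'   not an error.
#' @export
build_gold_standard <- function(records, window1, window2, threshold = 900,
                                std = standard_population(),
                                estimate_window = window2) {
  validate_person_records(records)
  yrs <- records$survey_year
  if (!any(yrs %in% window1) || !any(yrs %in% window2)) {
    stop("year windows do not overlap the data", call. = FALSE)
  }
  key <- interaction(records$area_id, records$sex, drop = TRUE)
  n1 <- tapply(yrs %in% window1, key, sum)
  n2 <- tapply(yrs %in% window2, key, sum)
  keep <- names(n1)[n1 > threshold & n2 > threshold]
  out <- data.frame(area_id = character(0), sex = character(0),
                    estimate = numeric(0), n_pooled = integer(0),
                    stringsAsFactors = FALSE)
  for (k in keep) {
    sub <- records[key == k & yrs %in% estimate_window, , drop = FALSE]
    if (nrow(sub) == 0) next
    out <- rbind(out, data.frame(
      area_id = sub$area_id[1], sex = sub$sex[1],
      estimate = direct_estimate(sub, std), n_pooled = nrow(sub),
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$sex, out$area_id), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    warning("no area met the gold-standard threshold in both windows",
            call. = FALSE)
  }
  attr(out, "years") <- estimate_window
  class(out) <- c("gold_standard", "data.frame")
  out
}
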
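#' Demographic schema for survey microdata
#'
#' The package works with person-level survey records classified into ten
#' five-year age groups (30-34 through 75+) and five mutually exclusive
#' race/ethnicity groups.  The reference categories used when fitting models
#' are ages 50-54 and White non-Hispanic, the largest groups in adult US
#' survey data.
#'
#' @return `age_groups()` and `race_groups()` return character vectors of the
#'   level labels in their canonical order; `age_reference()` and
#'   `race_reference()` return the reference level.
#' @examples
#' age_groups()
#' race_groups()
#' @export
age_groups <- function() {
  c("30-34", "35-39", "40-44", "45-49", "50-54",
    "55-59", "60-64", "65-69", "70-74", "75+")
}

#' @rdname age_groups
#' @export
race_groups <- function() {
  c("White", "Black", "AIAN", "Hispanic", "Asian")
}

#' @rdname age_groups
#' @export
age_reference <- function() "50-54"

#' @rdname age_groups
#' @export
race_reference <- function() "White"

#' Standard age distribution for age standardization
#'
#' A standard population assigns a nonnegative weight to each age group,
#' summing to one.  Prevalence standardized to a common age distribution is
#' comparable across areas with different age structures.  The built-in
#' default approximates the 2000 US age distribution for persons aged 30 and
#' older; any other distribution over the same age groups can be supplied
#' wherever a standard population is accepted.
#'
#' @param weights Optional named numeric vector over [age_groups()];
#'   nonnegative, summing to 1 after normalization.
#' @return Named numeric vector over all age groups, summing to 1.
#' @examples
#' std <- standard_population()
#' sum(std)
#' @export
standard_population <- function(weights = NULL) {
  if (is.null(weights)) {
    ## approximate 2000 US Census counts (millions), ages 30+
    weights <- c("30-34" = 20.5, "35-39" = 22.7, "40-44" = 22.4,
                 "45-49" = 20.1, "50-54" = 17.6, "55-59" = 13.5,
                 "60-64" = 10.8, "65-69" = 9.5, "70-74" = 8.9,
                 "75+" = 16.6)
  }
  if (!all(age_groups() %in% names(weights))) {
    stop("standard population must name every age group", call. = FALSE)
  }
  w <- as.numeric(weights[age_groups()])
  if (any(w < 0) || sum(w) <= 0) {
    stop("standard population weights must be nonnegative with positive sum",
         call. = FALSE)
  }
  stats::setNames(w / sum(w), age_groups())
}

## inverse logit / logit on the probability scale
invlogit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

## validate that a vector of labels is drawn from a schema; id context for errors
check_levels <- function(x, levels, what) {
  bad <- which(!(x %in% levels))
  if (length(bad) > 0) {
    stop(sprintf("unknown %s label '%s' at row %d", what, x[bad[1]], bad[1]),
         call. = FALSE)
  }
  invisible(TRUE)
}

## deterministic substream seed derived from a master seed; keeps values
## inside the 32-bit integer range
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset * 9973) %% 2147483629)
}
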
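#' Area-level covariate and composition tables
#'
#' A `county_table` carries, for each area, (i) the area-level covariates
#' `Z` entering the Covariate and Full models (e.g. poverty rate, share with
#' a college degree), (ii) the area's demographic composition as proportions
#' over age group x race group cells, used to aggregate person-level
#' predictions to area prevalence, and (iii) an optional population size.
#'
#' @param covariates data.frame with column `area_id`, optional column
#'   `population`, and one numeric column per area covariate.
#' @param composition 3-d numeric array `[area, age_group, race_group]` of
#'   cell proportions; each area's slice must be nonnegative and sum to 1
#'   (tolerance 1e-9).  Dimnames must match `covariates$area_id`,
#'   [age_groups()] and [race_groups()].
#' @return An object of class `county_table`.
#' @export
county_table <- function(covariates, composition) {
  stopifnot(is.data.frame(covariates), "area_id" %in% names(covariates))
  covariates$area_id <- as.character(covariates$area_id)
  if (anyDuplicated(covariates$area_id)) stop("duplicate area ids", call. = FALSE)
  stopifnot(length(dim(composition)) == 3)
  dn <- dimnames(composition)
  if (!setequal(dn[[1]], covariates$area_id) ||
      !identical(dn[[2]], age_groups()) || !identical(dn[[3]], race_groups())) {
    stop("composition dimnames must match area ids and demographic schemas",
         call. = FALSE)
  }
  composition <- composition[covariates$area_id, , , drop = FALSE]
  for (i in seq_along(covariates$area_id)) {
    sl <- composition[i, , ]
    if (any(sl < -1e-12) || abs(sum(sl) - 1) > 1e-9) {
      stop(sprintf("composition for area '%s' must be nonnegative and sum to 1",
                   covariates$area_id[i]), call. = FALSE)
    }
  }
  structure(list(covariates = covariates, composition = composition),
            class = "county_table")
}

#' @export
print.county_table <- function(x, ...) {
  cat(sprintf("county_table: %d areas, covariates: %s\n",
              nrow(x$covariates),
              paste(covariate_names(x), collapse = ", ")))
  invisible(x)
}

#' @rdname county_table
#' @param x A `county_table`.
#' @export
covariate_names <- function(x) {
  setdiff(names(x$covariates), c("area_id", "population"))
}

## Z row for one area as a named numeric vector (original scale)
county_z <- function(counties, area) {
  i <- match(area, counties$covariates$area_id)
  if (is.na(i)) stop(sprintf("area '%s' not in county table", area), call. = FALSE)
  unlist(counties$covariates[i, covariate_names(counties), drop = FALSE])
}

## age x race composition matrix for one area
county_composition <- function(counties, area) {
  if (!(area %in% dimnames(counties$composition)[[1]])) {
    stop(sprintf("no composition data for area '%s'", area), call. = FALSE)
  }
  counties$composition[area, , ]
}

#' Read and write county tables
#'
#' Two CSV files: a covariate file (`area_id`, `population`, covariate
#' columns) and a long-format composition file (`area_id`, `age_group`,
#' `race_group`, `proportion`).
#'
#' @param cov_path,comp_path CSV file paths.
#' @param counties A [county_table()].
#' @return `read_county_table` returns a [county_table()].
#' @export
read_county_table <- function(cov_path, comp_path) {
  cov <- utils::read.csv(cov_path, stringsAsFactors = FALSE,
                         colClasses = c(area_id = "character"))
  comp_long <- utils::read.csv(comp_path, stringsAsFactors = FALSE,
                               colClasses = c(area_id = "character"))
  check_levels(comp_long$age_group, age_groups(), "age_group")
  check_levels(comp_long$race_group, race_groups(), "race_group")
  areas <- cov$area_id
  comp <- array(0, dim = c(length(areas), 10L, 5L),
                dimnames = list(areas, age_groups(), race_groups()))
  comp[cbind(match(comp_long$area_id, areas),
             match(comp_long$age_group, age_groups()),
             match(comp_long$race_group, race_groups()))] <- comp_long$proportion
  county_table(cov, comp)
}

#' @rdname read_county_table
#' @export
write_county_table <- function(counties, cov_path, comp_path) {
  stopifnot(inherits(counties, "county_table"))
  utils::write.csv(counties$covariates, cov_path, row.names = FALSE)
  comp <- counties$composition
  long <- expand.grid(area_id = dimnames(comp)[[1]],
                      age_group = age_groups(), race_group = race_groups(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$proportion <- comp[cbind(match(long$area_id, dimnames(comp)[[1]]),
                                match(long$age_group, age_groups()),
                                match(long$race_group, race_groups()))]
  utils::write.csv(long, comp_path, row.names = FALSE)
  invisible(NULL)
}
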
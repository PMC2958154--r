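## demographic cells and aggregation weights for one area under a model:
## age x race cells weighted by standard age distribution x county race
## composition when the model includes race, age-only cells otherwise.
aggregation_cells <- function(model, area, std, counties) {
  if (model$spec$include_race) {
    if (is.null(counties)) {
      stop(sprintf("race-standardized aggregation for area '%s' needs composition data",
                   area), call. = FALSE)
    }
    comp <- county_composition(counties, area)
    race_margin <- colSums(comp)
    cells <- expand.grid(age_group = age_groups(), race_group = race_groups(),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    w <- as.numeric(outer(std, race_margin))
  } else {
    cells <- data.frame(age_group = age_groups(),
                        race_group = race_reference(),
                        stringsAsFactors = FALSE)
    w <- as.numeric(std)
  }
  list(cells = cells, weights = w / sum(w))
}

#' Aggregate a fitted model to an area prevalence
#'
#' Evaluates the inverse-logit of the model's linear predictor for every
#' demographic cell (age x race when the model includes race, age only
#' otherwise) and combines the cell probabilities using the standard age
#' distribution and the area's race composition as weights, renormalized to
#' one.  This is the model-based, age-standardized counterpart of the direct
#' estimator.
#'
#' @inheritParams predict_linear
#' @param std A [standard_population()].
#' @param counties A [county_table()]; required when the model includes race
#'   (for the area race composition) or area covariates for an area unseen
#'   at fit time.
#' @return Prevalence in (0, 1).
#' @export
aggregate_to_prevalence <- function(model, area, year,
                                    std = standard_population(),
                                    counties = NULL, spatial_covariate = NULL) {
  stopifnot(inherits(model, "sae_fit"))
  ag <- aggregation_cells(model, area, std, counties)
  X <- fixed_design(model, ag$cells, area, year, counties, spatial_covariate)
  eta <- as.numeric(X %*% model$fixed_effects) + ranef_contribution(model, area, year)
  sum(ag$weights * invlogit(eta))
}

#' Empirical credibility region for an area prevalence
#'
#' Draws model parameters from their approximate conditional distributions
#' -- fixed effects from a multivariate normal with the fitted mean and
#' covariance, and the area's random effects from normals with their
#' conditional means and variances, sampled independently of the fixed
#' effects -- aggregates each draw to an area prevalence via the same
#' demographic weighting as [aggregate_to_prevalence()], and returns the
#' empirical 2.5\% and 97.5\% values (order statistics at ranks
#' `ceiling(0.025 * draws)` and `ceiling(0.975 * draws)`).  The
#' random-effect SD itself is held fixed across draws.
#'
#' @inheritParams aggregate_to_prevalence
#' @param draws Number of parameter draws (>= 40).
#' @param seed Integer seed for the draws.
#' @return Named numeric vector `c(lo95, hi95)`.
#' @export
credibility_region <- function(model, area, year, draws = 1000, seed = 1,
                               std = standard_population(),
                               counties = NULL, spatial_covariate = NULL) {
  stopifnot(inherits(model, "sae_fit"))
  if (draws < 40) {
    stop("draws must be >= 40 for 2.5%/97.5% percentiles", call. = FALSE)
  }
  if (!isTRUE(model$converged)) {
    stop("credibility regions require a converged model", call. = FALSE)
  }
  ag <- aggregation_cells(model, area, std, counties)
  X <- fixed_design(model, ag$cells, area, year, counties, spatial_covariate)
  set.seed(seed)
  B <- MASS::mvrnorm(draws, mu = model$fixed_effects, Sigma = model$fixed_cov)
  ri_m <- model$ranef_mean[area]; ri_v <- model$ranef_var[area]
  if (is.na(ri_m)) { ri_m <- 0; ri_v <- model$sigma_delta^2 }
  delta <- stats::rnorm(draws, ri_m, sqrt(ri_v))
  if (!is.null(model$slope_mean)) {
    sl_m <- model$slope_mean[area]; sl_v <- model$slope_var[area]
    if (is.na(sl_m)) { sl_m <- 0; sl_v <- model$sigma_year^2 }
    delta <- delta + stats::rnorm(draws, sl_m, sqrt(sl_v)) *
      (year - model$year_center)
  }
  eta <- X %*% t(B)                        # cells x draws
  eta <- sweep(eta, 2, delta, "+")
  prev <- as.numeric(ag$weights %*% invlogit(eta))
  s <- sort(prev)
  c(lo95 = s[ceiling(0.025 * draws)], hi95 = s[ceiling(0.975 * draws)])
}

#' Area prevalence estimates with credibility intervals
#'
#' Convenience wrapper producing one row per area: the point estimate from
#' [aggregate_to_prevalence()] and the bounds from [credibility_region()].
#'
#' @inheritParams credibility_region
#' @param areas Character vector of area ids.
#' @param records Optional person records used to report per-area pooled
#'   sample sizes.
#' @return data.frame with columns `area_id`, `sex`, `year`, `point`,
#'   `lo95`, `hi95`, `n_pooled`.
#' @export
prevalence_estimates <- function(model, areas, year, draws = 1000, seed = 1,
                                 std = standard_population(),
                                 counties = NULL, spatial_covariate = NULL,
                                 records = NULL) {
  n_pooled <- if (is.null(records)) rep(NA_integer_, length(areas)) else {
    as.integer(table(factor(records$area_id, levels = areas)))
  }
  rows <- lapply(seq_along(areas), function(i) {
    a <- areas[i]
    ci <- credibility_region(model, a, year, draws = draws,
                             seed = substream_seed(seed, i),
                             std = std, counties = counties,
                             spatial_covariate = spatial_covariate)
    data.frame(area_id = a,
               sex = if (is.null(model$spec$sex)) NA_character_ else model$spec$sex,
               year = year,
               point = aggregate_to_prevalence(model, a, year, std, counties,
                                               spatial_covariate),
               lo95 = ci[["lo95"]], hi95 = ci[["hi95"]],
               n_pooled = n_pooled[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
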
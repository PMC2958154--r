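#' Configuration for the synthetic survey-data generator
#'
#' Defines the generative model behind the synthetic multi-year, multi-county
#' survey microdata: a binomial logit model with fixed age, race and year
#' effects, area-level covariate effects, and a county random intercept that
#' can be spatially correlated through one neighbor-averaging pass.  County
#' sample sizes follow a gamma-Poisson (negative-binomial-type) law with a
#' persistent county size factor, so most counties are small while a few are
#' large in every survey year -- the regime of national telephone surveys,
#' where over 80\% of counties contribute fewer than 100 respondents a year.
#'
#' @param n_counties Number of areas.
#' @param years Strictly increasing integer vector of survey years.
#' @param mean_sample_per_county_year Mean sample size per county-year.
#' @param sample_size_dispersion Nonnegative dispersion of the county size
#'   factor (variance of the mean-1 gamma factor); larger values give more
#'   skewed county sizes.  0 means equal expected sizes.
#' @param alpha Baseline log-odds for the reference cell (age 50-54, White,
#'   earliest year, covariates 0, random intercept 0).
#' @param beta_age Length-9 vector of non-reference age effects, in the order
#'   of [age_groups()] with the reference omitted.
#' @param beta_race Length-4 vector of non-reference race effects, in the
#'   order of [race_groups()] with the reference omitted.
#' @param beta_year Vector of year effects, one per non-reference year
#'   (reference = earliest year).
#' @param gamma Named vector of county covariate effects; the names become
#'   the covariate columns of the generated county table.
#' @param sigma_delta Standard deviation of the county random intercept.
#' @param spatial_mixing In [0, 1): weight of the neighbor mean in the
#'   spatial mixing pass applied to the random intercepts.
#' @param covariate_risk_correlation In [-1, 1]: correlation between each
#'   generated county covariate and the (standardized) random intercept.
#' @param weight_cv Coefficient of variation of the poststratification
#'   weights (mean 1 within each county-year).
#' @param sexes Sex labels to generate (equal probability).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `synth_config`.
#' @details The default effect sizes are calibrated to the scale reported for
#'   diagnosed adult diabetes in US county survey data: baseline prevalence
#'   near 8\%, age effects rising from about -1.6 (ages 30-34) to +0.85
#'   (70-74) on the logit scale, minority race effects of 0.4-0.85, a secular
#'   upward trend of about 0.04 per year, county covariates jointly worth
#'   0.2 SD on the logit scale, and a residual county intercept SD of 0.1,
#'   the scale of the residual county variation such surveys report.
#' @export
synth_config <- function(n_counties = 300,
                         years = 2000:2004,
                         mean_sample_per_county_year = 50,
                         sample_size_dispersion = 2,
                         alpha = -2.44,
                         beta_age = c(-1.6, -1.2, -0.8, -0.4,
                                      0.37, 0.62, 0.78, 0.85, 0.74),
                         beta_race = c(Black = 0.84, AIAN = 0.79,
                                       Hispanic = 0.66, Asian = 0.46),
                         beta_year = NULL,
                         gamma = c(poverty_rate = 0.14, college_share = -0.14),
                         sigma_delta = 0.1,
                         spatial_mixing = 0.4,
                         covariate_risk_correlation = 0.3,
                         weight_cv = 0.5,
                         sexes = c("male", "female"),
                         seed = 1L) {
  years <- as.integer(years)
  if (length(years) < 1 || (length(years) > 1 && any(diff(years) <= 0))) {
    stop("years must be a strictly increasing integer vector", call. = FALSE)
  }
  if (is.null(beta_year)) beta_year <- 0.04 * seq_len(length(years) - 1L)
  if (n_counties < 1) stop("n_counties must be positive", call. = FALSE)
  if (mean_sample_per_county_year <= 0) stop("mean sample size must be positive",
                                             call. = FALSE)
  if (sample_size_dispersion < 0) stop("sample_size_dispersion must be >= 0",
                                       call. = FALSE)
  if (length(beta_age) != 9) stop("beta_age must have length 9", call. = FALSE)
  if (length(beta_race) != 4) stop("beta_race must have length 4", call. = FALSE)
  if (length(beta_year) != length(years) - 1L) {
    stop("beta_year must have one entry per non-reference year", call. = FALSE)
  }
  if (sigma_delta < 0) stop("sigma_delta must be >= 0", call. = FALSE)
  if (spatial_mixing < 0 || spatial_mixing >= 1) {
    stop("spatial_mixing must be in [0, 1)", call. = FALSE)
  }
  if (abs(covariate_risk_correlation) > 1) {
    stop("covariate_risk_correlation must be in [-1, 1]", call. = FALSE)
  }
  if (weight_cv < 0) stop("weight_cv must be >= 0", call. = FALSE)
  if (is.null(names(gamma))) names(gamma) <- paste0("z", seq_along(gamma))
  structure(list(n_counties = as.integer(n_counties), years = years,
                 mean_sample_per_county_year = mean_sample_per_county_year,
                 sample_size_dispersion = sample_size_dispersion,
                 alpha = alpha, beta_age = beta_age, beta_race = beta_race,
                 beta_year = beta_year, gamma = gamma,
                 sigma_delta = sigma_delta, spatial_mixing = spatial_mixing,
                 covariate_risk_correlation = covariate_risk_correlation,
                 weight_cv = weight_cv, sexes = sexes,
                 seed = as.integer(seed)),
            class = "synth_config")
}

## full effect vectors over all levels (0 at the reference)
age_effects <- function(config) {
  stats::setNames(append(config$beta_age, 0,
                         after = match(age_reference(), age_groups()) - 1L),
                  age_groups())
}
race_effects <- function(config) {
  stats::setNames(append(config$beta_race, 0,
                         after = match(race_reference(), race_groups()) - 1L),
                  race_groups())
}
year_effects <- function(config) {
  stats::setNames(c(0, config$beta_year), as.character(config$years))
}

#' Simulate the latent ground truth for a synthetic survey
#'
#' Draws county random intercepts with the configured SD, applies one
#' neighbor-mixing pass (each intercept is replaced by a convex combination
#' of itself and its neighbors' mean, islands untouched, the field rescaled
#' back to the target SD), draws county covariates with the configured
#' correlation with the intercept, generates county age x race compositions,
#' and computes each county's exact age-standardized true prevalence at the
#' prediction year (the last configured year) by aggregating inverse-logit
#' cell probabilities.
#'
#' @param config A [synth_config()].
#' @param graph An [area_graph()] with `config$n_counties` areas.
#' @return Object of class `synthetic_truth` with elements `config`, `graph`,
#'   `counties` (a [county_table()]), `delta` (named vector of true county
#'   intercepts), `true_prevalence` (named vector, standardized to the
#'   default [standard_population()] and the county race composition), and
#'   `prediction_year`.
#' @export
simulate_truth <- function(config, graph) {
  stopifnot(inherits(config, "synth_config"), inherits(graph, "area_graph"))
  if (length(graph$areas) != config$n_counties) {
    stop("graph must have config$n_counties areas", call. = FALSE)
  }
  areas <- graph$areas
  n <- length(areas)
  set.seed(substream_seed(config$seed, 1L))

  ## county random intercepts: draw, one spatial mixing pass, rescale
  delta <- stats::rnorm(n)
  m <- config$spatial_mixing
  if (m > 0) {
    nb_mean <- vapply(seq_len(n), function(i) {
      nb <- graph$neighbors[[areas[i]]]
      if (length(nb) == 0) return(NA_real_)
      mean(delta[match(nb, areas)])
    }, numeric(1))
    mixed <- ifelse(is.na(nb_mean), delta, (1 - m) * delta + m * nb_mean)
    delta <- mixed
  }
  if (config$sigma_delta > 0) {
    delta <- delta / stats::sd(delta) * config$sigma_delta
  } else {
    delta <- rep(0, n)
  }
  names(delta) <- areas

  ## covariates correlated with the (standardized) intercept field
  rho <- config$covariate_risk_correlation
  dstd <- if (config$sigma_delta > 0) as.numeric(scale(delta)) else rep(0, n)
  p <- length(config$gamma)
  z <- sapply(seq_len(p), function(k) {
    rho * dstd + sqrt(1 - rho^2) * stats::rnorm(n)
  })
  z <- matrix(z, nrow = n, dimnames = list(NULL, names(config$gamma)))

  ## county age x race composition: Dirichlet variation around national margins
  age_base <- standard_population()
  race_base <- c(White = 0.72, Black = 0.09, AIAN = 0.01,
                 Hispanic = 0.11, Asian = 0.07)
  comp <- array(0, dim = c(n, 10L, 5L),
                dimnames = list(areas, age_groups(), race_groups()))
  for (i in seq_len(n)) {
    ag <- stats::rgamma(10, shape = 300 * age_base)
    rc <- stats::rgamma(5, shape = 25 * race_base)
    comp[i, , ] <- outer(ag / sum(ag), rc / sum(rc))
  }

  counties <- county_table(
    data.frame(area_id = areas, z, stringsAsFactors = FALSE), comp)

  ## exact standardized prevalence at the prediction year
  pred_year <- config$years[length(config$years)]
  ae <- age_effects(config); re <- race_effects(config)
  ye <- year_effects(config)[as.character(pred_year)]
  std <- standard_population()
  zg <- as.numeric(z %*% config$gamma)
  truep <- vapply(seq_len(n), function(i) {
    eta <- outer(ae, re, "+") + config$alpha + ye + zg[i] + delta[i]
    race_margin <- colSums(comp[i, , ])
    w <- outer(std, race_margin)
    sum(w / sum(w) * invlogit(eta))
  }, numeric(1))
  names(truep) <- areas

  structure(list(config = config, graph = graph, counties = counties,
                 delta = delta, true_prevalence = truep,
                 prediction_year = pred_year),
            class = "synthetic_truth")
}

#' Simulate person-level survey records from a synthetic truth
#'
#' County-year sample sizes are Poisson around the configured mean times a
#' persistent county size factor drawn from a mean-1 gamma law with the
#' configured dispersion (marginally a negative-binomial-type count law, so
#' the same counties are large in every year).  Each respondent's age and
#' race are drawn from the county composition, sex uniformly from the
#' configured sexes, the binary outcome from the inverse-logit of the
#' generative linear predictor, and positive poststratification weights from
#' a gamma law with the configured coefficient of variation, renormalized to
#' mean exactly 1 within each county-year.
#'
#' @param truth A [simulate_truth()] result.
#' @param n_override Optional named vector (area id -> count) forcing the
#'   per-county-year sample size for selected areas.
#' @return data.frame of person records with columns `area_id`, `sex`,
#'   `age_group`, `race_group`, `survey_year`, `outcome`, `weight`.
#' @export
simulate_survey <- function(truth, n_override = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  config <- truth$config
  if (length(config$years) == 0) stop("empty years list", call. = FALSE)
  areas <- truth$graph$areas
  n <- length(areas)
  yrs <- config$years
  set.seed(substream_seed(config$seed, 2L))

  d <- config$sample_size_dispersion
  lambda <- if (d > 0) stats::rgamma(n, shape = 1 / d, rate = 1 / d) else rep(1, n)
  counts <- matrix(stats::rpois(n * length(yrs),
                                config$mean_sample_per_county_year * lambda),
                   nrow = n)
  if (!is.null(n_override)) {
    i <- match(names(n_override), areas)
    if (anyNA(i)) stop("n_override names unknown area ids", call. = FALSE)
    counts[i, ] <- matrix(rep(as.integer(n_override), length(yrs)), ncol = length(yrs))
  }

  ae <- age_effects(config); re <- race_effects(config); ye <- year_effects(config)
  zg <- as.numeric(as.matrix(
    truth$counties$covariates[, names(config$gamma), drop = FALSE]) %*% config$gamma)

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    ni <- sum(counts[i, ])
    if (ni == 0) next
    comp_i <- truth$counties$composition[areas[i], , ]
    cell <- sample.int(50L, ni, replace = TRUE, prob = as.vector(comp_i))
    age_idx <- (cell - 1L) %% 10L + 1L
    race_idx <- (cell - 1L) %/% 10L + 1L
    year_i <- rep(yrs, counts[i, ])
    eta <- config$alpha + ae[age_idx] + re[race_idx] +
      ye[as.character(year_i)] + zg[i] + truth$delta[i]
    recs[[i]] <- data.frame(
      area_id = areas[i],
      sex = sample(config$sexes, ni, replace = TRUE),
      age_group = age_groups()[age_idx],
      race_group = race_groups()[race_idx],
      survey_year = year_i,
      outcome = stats::rbinom(ni, 1L, invlogit(unname(eta))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL

  cv <- config$weight_cv
  if (cv > 0) {
    w <- stats::rgamma(nrow(out), shape = 1 / cv^2, rate = 1 / cv^2)
    w <- pmax(w, 1e-8)
    cellkey <- paste(out$area_id, out$survey_year)
    out$weight <- w / stats::ave(w, cellkey)
  } else {
    out$weight <- 1
  }
  out
}

#' Write a synthetic dataset to a directory
#'
#' Writes the person records, county covariate and composition tables,
#' adjacency list, truth table, and a data dictionary describing every
#' column.
#'
#' @param truth A [simulate_truth()] result.
#' @param records Person records from [simulate_survey()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_synthetic <- function(truth, records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("persons.csv", "county_covariates.csv",
                                "county_composition.csv", "adjacency.txt",
                                "truth.csv", "data_dictionary.txt"))
  write_person_records(records, paths[1])
  write_county_table(truth$counties, paths[2], paths[3])
  write_adjacency(truth$graph, paths[4])
  utils::write.csv(data.frame(area_id = names(truth$delta),
                              delta = as.numeric(truth$delta),
                              true_prevalence = as.numeric(truth$true_prevalence),
                              prediction_year = truth$prediction_year),
                   paths[5], row.names = FALSE)
  writeLines(c(
    "persons.csv: one row per survey respondent",
    "  area_id      five-digit area (county) identifier",
    "  sex          male / female",
    paste0("  age_group    one of: ", paste(age_groups(), collapse = ", ")),
    paste0("  race_group   one of: ", paste(race_groups(), collapse = ", ")),
    "  survey_year  integer survey year",
    "  outcome      binary outcome (1 = condition present)",
    "  weight       positive poststratification weight, mean 1 per county-year",
    "county_covariates.csv: area_id plus one column per area-level covariate",
    "county_composition.csv: area_id, age_group, race_group, proportion",
    "  (proportions sum to 1 within each area)",
    "adjacency.txt: area_id<TAB>comma-separated neighbor ids ('' = island)",
    "truth.csv: area_id, delta (true county random intercept),",
    "  true_prevalence (age-standardized truth at prediction_year)"),
    paths[6])
  invisible(paths)
}
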
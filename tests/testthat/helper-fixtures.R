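# Small record builders shared across test files.

make_records <- function(area_id, age_group = "50-54", race_group = "White",
                         survey_year = 2004, outcome = 0, weight = 1,
                         sex = "female") {
  n <- length(area_id)
  data.frame(area_id = area_id, sex = rep_len(sex, n),
             age_group = rep_len(age_group, n),
             race_group = rep_len(race_group, n),
             survey_year = rep_len(survey_year, n),
             outcome = rep_len(outcome, n), weight = rep_len(weight, n),
             stringsAsFactors = FALSE)
}

# A hand-set fitted-model object exercising predict/aggregate arithmetic
# without an actual fit.
hand_model <- function(include_race = TRUE, fe_extra = NULL,
                       ranef = c(a1 = 0.2, a2 = -0.1)) {
  fe <- c(intercept = -2,
          stats::setNames(seq(-0.9, 0.9, length.out = 9)[c(1:4, 5:9)],
                          paste0("age:", setdiff(age_groups(), age_reference()))))
  if (include_race) {
    fe <- c(fe, stats::setNames(c(0.5, 0.4, 0.3, 0.2),
                                paste0("race:", setdiff(race_groups(), race_reference()))))
  }
  fe <- c(fe, "year:2004" = 0.1)
  if (!is.null(fe_extra)) fe <- c(fe, fe_extra)
  V <- matrix(0, length(fe), length(fe), dimnames = list(names(fe), names(fe)))
  structure(list(
    spec = model_spec(if (is.null(fe_extra)) "naive" else "covariate",
                      include_race = include_race),
    fixed_effects = fe,
    fixed_cov = V,
    sigma_delta = 0.2, ranef_mean = ranef,
    ranef_var = stats::setNames(rep(0, length(ranef)), names(ranef)),
    slope_mean = NULL, slope_var = NULL,
    loglik = NA_real_, converged = TRUE, n_used = 0L,
    year_levels = c(2003L, 2004L), year_center = 2003.5,
    z_names = character(0), z_by_area = NULL, spatial_values = NULL),
    class = "sae_fit")
}

# A small synthetic dataset reused by several test files (cheap to build).
tiny_world <- local({
  built <- NULL
  function() {
    if (is.null(built)) {
      sc <- synth_config(n_counties = 64, years = 2002:2004,
                         mean_sample_per_county_year = 30,
                         sample_size_dispersion = 1, sexes = "female",
                         seed = 99)
      g <- make_county_graph(64, n_islands = 1, seed = 99)
      tr <- simulate_truth(sc, g)
      recs <- simulate_survey(tr)
      built <<- list(config = sc, graph = g, truth = tr, records = recs)
    }
    built
  }
})
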
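test_that("config invariants are enforced", {
  expect_error(synth_config(years = c(2004, 2002)), "increasing")
  expect_error(synth_config(beta_age = rep(0, 3)), "length 9")
  expect_error(synth_config(sigma_delta = -1), "sigma_delta")
  expect_error(synth_config(spatial_mixing = 1), "spatial_mixing")
  expect_error(synth_config(years = 2000:2004, beta_year = c(0, 0)),
               "non-reference year")
})

test_that("zero intercept variance gives a flat random-effect field", {
  sc <- synth_config(n_counties = 25, years = 2004, beta_year = numeric(0),
                     sigma_delta = 0, seed = 4)
  g <- make_county_graph(25, 0, seed = 4)
  tr <- simulate_truth(sc, g)
  expect_true(all(tr$delta == 0))
  expect_true(all(tr$true_prevalence > 0 & tr$true_prevalence < 1))
})

test_that("true prevalence equals an independent cell-level aggregation", {
  w <- tiny_world()
  tr <- w$truth; sc <- w$config
  std <- standard_population()
  ae <- c(sc$beta_age[1:4], 0, sc$beta_age[5:9])
  re <- c(0, sc$beta_race)
  yr_eff <- c(0, sc$beta_year)[length(sc$years)]
  for (a in sample(tr$graph$areas, 5)) {
    comp <- tr$counties$composition[a, , ]
    z <- unlist(tr$counties$covariates[
      match(a, tr$counties$covariates$area_id), names(sc$gamma)])
    expected <- 0; wsum <- 0
    for (i in 1:10) for (j in 1:5) {
      wt <- unname(std[i]) * sum(comp[, j])
      p <- unname(plogis(sc$alpha + ae[i] + re[j] + yr_eff +
                           sum(z * sc$gamma) + tr$delta[[a]]))
      expected <- expected + wt * p
      wsum <- wsum + wt
    }
    expect_equal(unname(tr$true_prevalence[a]), expected / wsum,
                 tolerance = 1e-12)
  }
})

test_that("spatial mixing controls the neighbor correlation of the field", {
  ## independent field: neighbor-mean correlation near zero
  sc0 <- synth_config(n_counties = 1024, years = 2004, beta_year = numeric(0),
                      sigma_delta = 0.3, spatial_mixing = 0, seed = 11)
  g0 <- make_county_graph(1024, 0, seed = 11)
  tr0 <- simulate_truth(sc0, g0)
  nbm0 <- vapply(g0$areas, function(a) mean(tr0$delta[g0$neighbors[[a]]]),
                 numeric(1))
  expect_lt(abs(cor(tr0$delta, nbm0)), 0.1)

  ## strongly mixed field: Moran-type correlation above 0.5
  sc1 <- synth_config(n_counties = 400, years = 2004, beta_year = numeric(0),
                      sigma_delta = 0.3, spatial_mixing = 0.8, seed = 12)
  g1 <- make_county_graph(400, 0, seed = 12)
  tr1 <- simulate_truth(sc1, g1)
  nbm1 <- vapply(g1$areas, function(a) mean(tr1$delta[g1$neighbors[[a]]]),
                 numeric(1))
  expect_gt(cor(tr1$delta, nbm1), 0.5)
  ## rescaling preserves the target marginal SD
  expect_equal(sd(tr1$delta), 0.3, tolerance = 1e-12)
})

test_that("survey generation is reproducible and respects cell weight means", {
  w <- tiny_world()
  r1 <- simulate_survey(w$truth)
  expect_identical(r1, w$records)
  cellmeans <- tapply(r1$weight, paste(r1$area_id, r1$survey_year), mean)
  expect_true(all(abs(cellmeans - 1) < 1e-12))
  expect_true(all(r1$weight > 0))
  ## a different seed changes the data
  sc2 <- w$config; sc2$seed <- 1234L
  tr2 <- simulate_truth(sc2, w$graph)
  expect_false(identical(simulate_survey(tr2), r1))
})

test_that("null generative model reproduces the baseline prevalence", {
  sc <- synth_config(n_counties = 200, years = 2004, beta_year = numeric(0),
                     mean_sample_per_county_year = 1000,
                     sample_size_dispersion = 0,
                     alpha = qlogis(0.1), beta_age = rep(0, 9),
                     beta_race = rep(0, 4), gamma = c(z1 = 0),
                     sigma_delta = 0, spatial_mixing = 0,
                     covariate_risk_correlation = 0, weight_cv = 0,
                     sexes = "female", seed = 21)
  g <- make_county_graph(200, 0, seed = 21)
  recs <- simulate_survey(simulate_truth(sc, g))
  expect_gt(nrow(recs), 150000)
  expect_gt(mean(recs$outcome), 0.097)
  expect_lt(mean(recs$outcome), 0.103)
})

test_that("county size law is right-skewed with persistent large counties", {
  sc <- synth_config(n_counties = 400, years = 2000:2004,
                     mean_sample_per_county_year = 20,
                     sample_size_dispersion = 2, sexes = "female", seed = 31)
  g <- make_county_graph(400, 0, seed = 31)
  recs <- simulate_survey(simulate_truth(sc, g))
  n_cy <- table(factor(paste(recs$area_id, recs$survey_year),
                       levels = as.vector(outer(g$areas, sc$years, paste))))
  expect_gt(mean(n_cy < 20), 0.6)
  expect_gt(max(n_cy), 100)
})

test_that("a forced huge county recovers its own random intercept", {
  sc <- synth_config(n_counties = 16, years = 2004, beta_year = numeric(0),
                     mean_sample_per_county_year = 30,
                     alpha = -2.3, sigma_delta = 0.4, spatial_mixing = 0,
                     weight_cv = 0, sexes = "female", seed = 41)
  g <- make_county_graph(16, 0, seed = 41)
  tr <- simulate_truth(sc, g)
  a <- g$areas[1]
  recs <- simulate_survey(tr, n_override = stats::setNames(50000, a))
  sub <- recs[recs$area_id == a, ]
  expect_identical(nrow(sub), 50000L)
  ## empirical mean vs exact composition-weighted cell aggregation
  comp <- tr$counties$composition[a, , ]
  ae <- c(sc$beta_age[1:4], 0, sc$beta_age[5:9])
  re <- c(0, sc$beta_race)
  z <- unlist(tr$counties$covariates[match(a, tr$counties$covariates$area_id),
                                     names(sc$gamma)])
  p_cell <- plogis(outer(ae, re, "+") + sc$alpha + sum(z * sc$gamma) + tr$delta[a])
  p_expected <- sum(comp * p_cell)
  se <- sqrt(p_expected * (1 - p_expected) / 50000)
  expect_lt(abs(mean(sub$outcome) - p_expected), 4 * se)
})

test_that("synthetic datasets round-trip through the writers", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  paths <- write_synthetic(w$truth, w$records, dir)
  expect_true(all(file.exists(paths)))
  recs <- read_person_records(file.path(dir, "persons.csv"))
  expect_equal(recs, w$records, tolerance = 1e-12)
  ct <- read_county_table(file.path(dir, "county_covariates.csv"),
                          file.path(dir, "county_composition.csv"))
  expect_equal(ct$composition, w$truth$counties$composition, tolerance = 1e-9)
  expect_identical(read_adjacency(file.path(dir, "adjacency.txt")), w$graph)
})
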
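## small simulated dataset with a real area effect, reused below
glmm_data <- local({
  built <- NULL
  function() {
    if (is.null(built)) {
      set.seed(17)
      n_area <- 40; n_per <- 60
      areas <- sprintf("%05d", seq_len(n_area))
      area <- rep(areas, each = n_per)
      delta <- rnorm(n_area, 0, 0.4)
      z1 <- rnorm(n_area)
      yr <- sample(2003:2004, n_area * n_per, TRUE)
      eta <- -1.5 + 0.5 * z1[match(area, areas)] + 0.1 * (yr == 2004) +
        delta[match(area, areas)]
      recs <- make_records(area, survey_year = yr,
                           outcome = rbinom(length(eta), 1, plogis(eta)))
      counties <- county_table(
        data.frame(area_id = areas, z1 = z1, stringsAsFactors = FALSE),
        flat_composition(areas))
      built <<- list(records = recs, counties = counties, delta = delta)
    }
    built
  }
})

flat_composition <- function(areas) {
  comp <- array(1 / 50, dim = c(length(areas), 10, 5),
                dimnames = list(areas, age_groups(), race_groups()))
  comp
}

test_that("degenerate inputs are rejected", {
  recs <- make_records(rep("00001", 20), outcome = rep(0:1, 10))
  expect_error(fit_glmm(recs, model_spec("naive")), "single area")
  recs2 <- make_records(rep(c("00001", "00002"), 10), outcome = 0)
  expect_error(fit_glmm(recs2, model_spec("naive")), "constant")
  expect_error(fit_glmm(glmm_data()$records, model_spec("covariate")),
               "county table")
})

test_that("covariate shift equivariance: recentering Z moves only the intercept", {
  d <- glmm_data()
  spec <- model_spec("covariate", include_age = FALSE)
  f1 <- fit_glmm(d$records, spec, counties = d$counties)
  shifted <- d$counties
  shifted$covariates$z1 <- shifted$covariates$z1 + 5
  f2 <- fit_glmm(d$records, spec, counties = shifted)
  gam <- f1$fixed_effects[["z:z1"]]
  expect_equal(f2$fixed_effects[["z:z1"]], gam, tolerance = 1e-4)
  expect_equal(f2$fixed_effects[["intercept"]],
               f1$fixed_effects[["intercept"]] - 5 * gam, tolerance = 1e-4)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("conditional means shrink more for areas with fewer observations", {
  ## two areas with identical empirical prevalence but 10x sample size
  set.seed(23)
  filler <- make_records(rep(sprintf("f%02d", 1:20), each = 40),
                         outcome = rbinom(800, 1, 0.2))
  big <- make_records(rep("big01", 400), outcome = rep(c(1, 0, 0, 0), 100))
  small <- make_records(rep("sml01", 40), outcome = rep(c(1, 0, 0, 0), 10))
  fit <- fit_glmm(rbind(filler, big, small), model_spec("naive", include_age = FALSE))
  expect_gt(abs(fit$ranef_mean[["big01"]]), abs(fit$ranef_mean[["sml01"]]))
  ## and every area fitted has a conditional mean and variance
  expect_setequal(names(fit$ranef_mean), unique(c(filler$area_id, "big01", "sml01")))
  expect_true(all(fit$ranef_var > 0))
})

test_that("linear predictor matches hand-summed coefficients exactly", {
  m <- hand_model(fe_extra = c("z:pov" = 0.3))
  m$z_names <- "pov"
  m$z_by_area <- data.frame(area_id = c("a1", "a2"), pov = c(2, -1),
                            stringsAsFactors = FALSE)
  ## reference cell in an area with ranef 0.2 and z = 2
  eta <- predict_linear(m, "a1", "50-54", "White", 2003)
  expect_equal(eta, -2 + 0.3 * 2 + 0.2, tolerance = 1e-12)
  ## non-reference everything
  eta2 <- predict_linear(m, "a2", "30-34", "Black", 2004)
  expect_equal(eta2,
               -2 + m$fixed_effects[["age:30-34"]] + 0.5 + 0.1 + 0.3 * (-1) - 0.1,
               tolerance = 1e-12)
  ## unseen area differs by exactly the seen area's ranef
  m$z_by_area <- rbind(m$z_by_area,
                       data.frame(area_id = "new", pov = 2))
  eta3 <- predict_linear(m, "new", "50-54", "White", 2003)
  expect_equal(eta - eta3, 0.2, tolerance = 1e-12)
  ## unseen demographic level errors
  expect_error(predict_linear(m, "a1", "20-24", "White", 2003), "age_group")
  expect_error(predict_linear(m, "a1", "50-54", "White", 1990), "unseen")
})

test_that("reference cell with centered covariates returns the intercept", {
  m <- hand_model()
  m$ranef_mean <- c(a1 = 0, a2 = -0.1)
  expect_equal(predict_linear(m, "a1", "50-54", "White", 2003),
               m$fixed_effects[["intercept"]], tolerance = 1e-12)
})

test_that("random year effect fits an independent slope per area", {
  set.seed(29)
  areas <- sprintf("%05d", 1:30)
  area <- rep(areas, each = 80)
  yr <- rep(rep(2000:2003, each = 20), 30)
  slope <- rnorm(30, 0.05, 0.15)
  eta <- -1.2 + slope[match(area, areas)] * (yr - 2001.5)
  recs <- make_records(area, survey_year = yr,
                       outcome = rbinom(length(eta), 1, plogis(eta)))
  fit <- fit_glmm(recs, model_spec("naive", year_effect = "random",
                                   include_age = FALSE))
  expect_true(!is.null(fit$slope_mean))
  expect_gt(fit$sigma_year, 0.02)
  ## prediction uses the area slope: two years differ by trend + slope
  a <- areas[1]
  d <- predict_linear(fit, a, "50-54", "White", 2003) -
    predict_linear(fit, a, "50-54", "White", 2000)
  expect_equal(d, 3 * (fit$fixed_effects[["year_trend"]] + fit$slope_mean[[a]]),
               tolerance = 1e-10)
})
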
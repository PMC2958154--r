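test_that("concordance matches hand-evaluated and oracle values", {
  expect_equal(ccc(c(1, 5, 3), c(1, 5, 3)), 1, tolerance = 1e-15)
  ## means 2, 4; population variances 2/3, 8/3; covariance 4/3 -> 8/22
  expect_equal(ccc(c(1, 2, 3), c(2, 4, 6)), 8 / 22, tolerance = 1e-15)
  ## location shift strictly penalized relative to Pearson correlation
  x <- c(0.3, 0.5, 0.9)
  expect_lt(ccc(x, x + 0.2), 1)
  expect_equal(cor(x, x + 0.2), 1, tolerance = 1e-12)
  expect_error(ccc(c(1, 1), c(1, 1)), "undefined")
  expect_error(ccc(1:3, 1:4), "equal length")
})

test_that("concordance equals Pearson times the bias-correction factor", {
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(20); y <- 0.6 * x + rnorm(20, 0.2, 0.5)
    expect_equal(ccc(x, y), ccc_oracle(x, y), tolerance = 1e-12)
    ## permutation invariance
    p <- sample(20)
    expect_equal(ccc(x[p], y[p]), ccc(x, y), tolerance = 1e-12)
  }
})

test_that("rmse matches its definition and is homogeneous", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(0.1, -0.1)), 0.1, tolerance = 1e-15)
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(rmse(3 * x, 3 * y), 3 * rmse(x, y), tolerance = 1e-12)
  p <- sample(10)
  expect_equal(rmse(x[p], y[p]), rmse(x, y), tolerance = 1e-12)
  expect_error(rmse(1:2, 1:3), "equal length")
})

test_that("downsampling draws exactly level records per area-year", {
  w <- tiny_world()
  recs <- w$records
  areas <- unique(recs$area_id)
  sub <- downsample_records(recs, 7, seed = 3)
  tab <- table(sub$area_id, sub$survey_year)
  expect_true(all(tab[cbind(as.character(recs$area_id),
                            as.character(recs$survey_year))] == 7))
  expect_true(all(tab[tab > 0] == 7))
  ## determinism and seed sensitivity
  expect_identical(downsample_records(recs, 7, seed = 3), sub)
  expect_false(identical(downsample_records(recs, 7, seed = 4), sub))
  ## level above the cell size still returns exactly level rows
  small <- recs[recs$area_id == areas[1], ]
  big <- downsample_records(small, 500, seed = 1)
  expect_identical(nrow(big), 500L * length(unique(small$survey_year)))
  expect_true(any(duplicated(big)))  # with-replacement duplicates
  ## an expected-but-empty cell is an error naming the cell
  expect_error(downsample_records(small, 5, seed = 1,
                                  areas = c(areas[1], "99999"),
                                  years = unique(small$survey_year)),
               "99999")
})

test_that("experiment row layout matches specs x levels x replicates", {
  w <- tiny_world()
  gold <- build_gold_standard(w$records, 2002:2003, 2003:2004, threshold = 60)
  specs <- list(model_spec("naive"))
  res <- run_experiment(w$records, gold, specs, levels = 20, replicates = 3,
                        target_year = 2004, graph = w$graph, seed = 5)
  expect_identical(nrow(res), 4L)  # 3 replicates + one "all" row
  expect_identical(sum(res$level == "all"), 1L)
  expect_true(all(res$n_areas == nrow(gold)))
  expect_true(all(res$ccc[res$converged] > -1 & res$ccc[res$converged] <= 1))
  ## bit-reproducible under the same seed
  res2 <- run_experiment(w$records, gold, specs, levels = 20, replicates = 3,
                         target_year = 2004, graph = w$graph, seed = 5)
  expect_identical(res, res2)
})

test_that("direct baseline scores one row per level-replicate plus all", {
  w <- tiny_world()
  gold <- build_gold_standard(w$records, 2002:2003, 2003:2004, threshold = 60)
  recs04 <- w$records[w$records$survey_year == 2004, ]
  base <- score_direct_baseline(recs04, gold, levels = c(20, 5),
                                replicates = 2, seed = 9)
  expect_identical(nrow(base), 5L)
  expect_true(all(base$family == "direct"))
  expect_error(score_direct_baseline(w$records, gold, levels = 20,
                                     replicates = 1),
               "single")
})

test_that("model ranking uses mean concordance with an RMSE tie-break", {
  row <- function(fam, race, ccc, rmse, conv = TRUE) {
    data.frame(family = fam, include_race = race, year_effect = "fixed",
               sex = "female", level = "10", replicate = 1L, ccc = ccc,
               rmse = rmse, n_areas = 5L, converged = conv,
               stringsAsFactors = FALSE)
  }
  res <- rbind(row("naive", FALSE, 0.8, 0.05), row("naive", FALSE, 0.6, 0.05),
               row("covariate", FALSE, 0.8, 0.03), row("covariate", FALSE, 0.6, 0.03),
               row("full", FALSE, 0.5, 0.01, conv = FALSE),
               row("direct", FALSE, 0.99, 0.001))
  rk <- rank_models(res)
  ## equal mean ccc (0.7): covariate wins on lower rmse; direct not ranked
  expect_identical(rk$family[1], "covariate")
  expect_identical(attr(rk, "best")$family, "covariate")
  expect_false("direct" %in% rk$family)
  expect_identical(rk$n_nonconverged[rk$family == "full"], 1L)
  ## non-converged-only input errors
  expect_error(rank_models(row("naive", FALSE, NA, NA, conv = FALSE)),
               "converged")
})
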
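#' Configuration for the end-to-end pipeline
#'
#' Bundles the constants of the measurement-and-validation run: which model
#' specifications to evaluate, the downsampling levels and replicate count,
#' the gold-standard windows and threshold, the prediction year, and the
#' master seed from which every stage derives its own substream.
#'
#' @param synth A [synth_config()] describing the synthetic data to
#'   generate, or `NULL` to read data from `paths`.
#' @param paths Named list with elements `persons`, `county_covariates`,
#'   `county_composition`, `adjacency` when `synth` is `NULL`.
#' @param families,include_race,year_effect Passed to [enumerate_specs()].
#' @param levels Positive, strictly decreasing sampling levels.
#' @param replicates Replicates per level (>= 1).
#' @param threshold Gold-standard sample-size threshold.
#' @param window1,window2 Gold-standard pooling windows (defaults: first and
#'   second half-overlapping halves of the data years for synthetic runs).
#' @param target_year Prediction/comparison year (default: last data year).
#' @param draws Parameter draws for credibility regions.
#' @param n_islands Island areas in the generated contiguity graph.
#' @param seed Master seed.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), paths = NULL,
                       families = c("naive", "geospatial", "covariate", "full"),
                       include_race = c(FALSE, TRUE),
                       year_effect = c("fixed", "random"),
                       levels = c(100, 50, 10), replicates = 10,
                       threshold = 900, window1 = NULL, window2 = NULL,
                       target_year = NULL, draws = 1000, n_islands = 0,
                       seed = 1, out_dir = NULL) {
  if (any(levels <= 0) || (length(levels) > 1 && any(diff(levels) >= 0))) {
    stop("levels must be positive and strictly decreasing", call. = FALSE)
  }
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (is.null(synth) && is.null(paths)) {
    stop("either synth or paths must be given", call. = FALSE)
  }
  structure(list(synth = synth, paths = paths, families = families,
                 include_race = include_race, year_effect = year_effect,
                 levels = levels, replicates = replicates,
                 threshold = threshold, window1 = window1, window2 = window2,
                 target_year = target_year, draws = draws,
                 n_islands = n_islands, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full measurement-and-validation pipeline
#'
#' Generates (or reads) the survey data, builds the per-sex gold standard,
#' runs the downsampling validation experiment and the single-year direct
#' baseline, ranks the model specifications, refits the best specification
#' per sex on the full data, and produces per-area prevalence estimates
#' with empirical credibility intervals.  With a fixed configuration and
#' seed the run is reproducible; outputs are written as tidy CSV tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `validation` (including baseline rows),
#'   `ranking` (per sex), `gold`, `prevalence`, `counties`, `graph`, and
#'   `truth` (synthetic runs only).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$synth)) {
    sc <- config$synth
    sc$seed <- substream_seed(config$seed, 100L)
    graph <- make_county_graph(sc$n_counties, config$n_islands,
                               seed = substream_seed(config$seed, 101L))
    truth <- simulate_truth(sc, graph)
    records <- simulate_survey(truth)
    counties <- truth$counties
  } else {
    records <- read_person_records(config$paths$persons)
    counties <- read_county_table(config$paths$county_covariates,
                                  config$paths$county_composition)
    graph <- read_adjacency(config$paths$adjacency)
    truth <- NULL
  }
  yrs <- sort(unique(records$survey_year))
  target_year <- if (is.null(config$target_year)) yrs[length(yrs)] else config$target_year
  half <- ceiling(length(yrs) / 2)
  window1 <- if (is.null(config$window1)) yrs[seq_len(half)] else config$window1
  window2 <- if (is.null(config$window2)) {
    yrs[seq(length(yrs) - half + 1, length(yrs))]
  } else config$window2
  std <- standard_population()

  gold <- build_gold_standard(records, window1, window2, config$threshold,
                              std = std)
  specs <- enumerate_specs(config$families, config$include_race,
                           config$year_effect)

  validation <- list(); ranking <- list(); prevalence <- list()
  for (sex in sort(unique(records$sex))) {
    gold_s <- gold[gold$sex == sex, , drop = FALSE]
    if (nrow(gold_s) == 0) next
    res <- run_experiment(records, gold_s, specs, config$levels,
                          config$replicates, target_year,
                          counties = counties, graph = graph, std = std,
                          seed = substream_seed(config$seed, 200L))
    base <- score_direct_baseline(
      records[records$survey_year == target_year, , drop = FALSE], gold_s,
      config$levels, config$replicates, std = std,
      seed = substream_seed(config$seed, 300L))
    validation[[sex]] <- rbind(res, base)
    rk <- rank_models(res)
    ranking[[sex]] <- cbind(sex = sex, as.data.frame(rk))
    best <- attr(rk, "best")
    best$sex <- sex
    fit <- fit_family(records, best, counties = counties, graph = graph)
    prevalence[[sex]] <- prevalence_estimates(
      fit, graph$areas, target_year, draws = config$draws,
      seed = substream_seed(config$seed, 400L), std = std,
      counties = counties,
      records = records[records$sex == sex, , drop = FALSE])
  }
  validation <- do.call(rbind, unname(validation))
  ranking <- do.call(rbind, unname(ranking))
  prevalence <- do.call(rbind, unname(prevalence))
  rownames(validation) <- rownames(ranking) <- rownames(prevalence) <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(validation, file.path(config$out_dir, "validation.csv"),
                     row.names = FALSE)
    utils::write.csv(ranking, file.path(config$out_dir, "ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(gold),
                     file.path(config$out_dir, "gold_standard.csv"),
                     row.names = FALSE)
    utils::write.csv(prevalence, file.path(config$out_dir, "prevalence.csv"),
                     row.names = FALSE)
  }
  invisible(list(validation = validation, ranking = ranking, gold = gold,
                 prevalence = prevalence, counties = counties, graph = graph,
                 truth = truth))
}
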
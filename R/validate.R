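#' Lin's concordance correlation coefficient
#'
#' Measures agreement between two vectors, penalizing both imprecision and
#' location/scale shift: `2 cov(x, y) / (var(x) + var(y) + (mean(x) -
#' mean(y))^2)`, with population (1/n) moments.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Value in [-1, 1].
#' @examples
#' ccc(c(1, 2, 3), c(2, 4, 6))  # 8/22
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) stop("concordance undefined for identical constant vectors",
                       call. = FALSE)
  2 * cxy / denom
}

#' Root mean squared error
#'
#' @param x,y Numeric vectors of equal length >= 1.
#' @return `sqrt(mean((x - y)^2))`.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 1) stop("need at least one observation", call. = FALSE)
  sqrt(mean((x - y)^2))
}

#' Downsample records to a fixed size per area-year
#'
#' Samples exactly `level` records with replacement, independently within
#' every area x survey-year cell, emulating the systematic reduction of the
#' information available from large-sample areas.
#'
#' @param records Person records (already restricted to the areas of
#'   interest).
#' @param level Records to draw per area-year cell.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param areas,years Optional expected area ids / years; any expected
#'   area-year cell with no records is an error naming the cell.
#' @return data.frame of person records with `level` rows per area-year.
#' @export
downsample_records <- function(records, level, seed = 1,
                               areas = NULL, years = NULL) {
  stopifnot(level >= 1)
  cellkey <- paste(records$area_id, records$survey_year, sep = "\r")
  cells <- unique(cellkey)
  if (!is.null(areas) && !is.null(years)) {
    expected <- as.vector(outer(areas, years, paste, sep = "\r"))
    missing_cell <- setdiff(expected, cells)
    if (length(missing_cell) > 0) {
      stop(sprintf("empty area-year cell: %s",
                   sub("\r", " / ", missing_cell[1])), call. = FALSE)
    }
    cells <- expected
  }
  set.seed(seed)
  idx <- unlist(lapply(cells, function(k) {
    pool <- which(cellkey == k)
    pool[sample.int(length(pool), level, replace = TRUE)]
  }), use.names = FALSE)
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## label for a spec in validation result tables
spec_label <- function(spec) {
  sprintf("%s|race=%d|year=%s", spec$family, as.integer(spec$include_race),
          spec$year_effect)
}

## one scored row of a validation result
score_row <- function(spec, level, replicate, est, gold_est, sex, converged = TRUE) {
  data.frame(family = spec$family, include_race = spec$include_race,
             year_effect = spec$year_effect, sex = sex,
             level = as.character(level), replicate = replicate,
             ccc = if (converged) ccc(est, gold_est) else NA_real_,
             rmse = if (converged) rmse(est, gold_est) else NA_real_,
             n_areas = length(gold_est), converged = converged,
             stringsAsFactors = FALSE)
}

#' Run the downsampling validation experiment
#'
#' For every model specification, sampling level, and replicate: draw a
#' with-replacement downsample of the gold-standard areas' records, fit the
#' model family on the reduced data, aggregate to standardized prevalence
#' for the target year in every gold-standard area, and score concordance
#' (CCC) and RMSE against the gold standard.  One additional `"all"` row
#' per specification uses the full (non-downsampled) data.  Fits that fail
#' or do not converge are recorded as flagged rows with missing scores,
#' never dropped silently.
#'
#' @param records Person records of one sex.
#' @param gold A [build_gold_standard()] result for the same sex.
#' @param specs List of [model_spec()] (see [enumerate_specs()]).
#' @param levels Integer vector of per-county-year sampling levels, e.g.
#'   `c(100, 50, 10)`.
#' @param replicates Replicates per level.
#' @param target_year Year for which prevalence is predicted and compared.
#' @param counties A [county_table()].
#' @param graph An [area_graph()] (needed by geospatial/full families).
#' @param std A [standard_population()].
#' @param seed Integer master seed.
#' @return data.frame of class `validation_result`: one row per spec x level
#'   x replicate plus the `"all"` rows, with columns `family`,
#'   `include_race`, `year_effect`, `sex`, `level`, `replicate`, `ccc`,
#'   `rmse`, `n_areas`, `converged`.
#' @export
run_experiment <- function(records, gold, specs, levels = c(100, 50, 10),
                           replicates = 10, target_year,
                           counties = NULL, graph = NULL,
                           std = standard_population(), seed = 1) {
  if (nrow(gold) == 0) stop("empty gold standard", call. = FALSE)
  if (length(unique(gold$sex)) > 1) {
    stop("run_experiment expects a single-sex gold standard", call. = FALSE)
  }
  sex <- gold$sex[1]
  if ("sex" %in% names(records)) {
    records <- records[records$sex == sex, , drop = FALSE]
  }
  gold_areas <- gold$area_id
  records <- records[records$area_id %in% gold_areas, , drop = FALSE]
  gold_est <- gold$estimate

  score_fit <- function(spec, data, level, replicate) {
    fit <- tryCatch(fit_family(data, spec, counties = counties, graph = graph),
                    error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      return(score_row(spec, level, replicate, NULL, gold_est, sex,
                       converged = FALSE))
    }
    est <- vapply(gold_areas, function(a) {
      aggregate_to_prevalence(fit, a, target_year, std, counties)
    }, numeric(1))
    score_row(spec, level, replicate, est, gold_est, sex)
  }

  rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    spec$sex <- sex
    rows[[length(rows) + 1]] <- score_fit(spec, records, "all", 1L)
    for (li in seq_along(levels)) {
      for (r in seq_len(replicates)) {
        sub <- downsample_records(records, levels[li],
                                  seed = substream_seed(seed, li * 1000 + r))
        rows[[length(rows) + 1]] <- score_fit(spec, sub, levels[li], r)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_result", "data.frame")
  out
}

#' Score the single-year direct estimator as a baseline
#'
#' Runs the same downsampling experiment with the single-year direct
#' (weighted, age-standardized) estimator in place of a model: per level and
#' replicate, the target-year records of every gold-standard area are
#' downsampled and the direct estimate is compared against the gold
#' standard.  One `"all"` row uses the full target-year data.
#'
#' @param records Person records for the target year only (one sex).
#' @inheritParams run_experiment
#' @return data.frame of baseline rows in the [run_experiment()] layout,
#'   with `family = "direct"`.
#' @export
score_direct_baseline <- function(records, gold, levels = c(100, 50, 10),
                                  replicates = 10,
                                  std = standard_population(), seed = 1) {
  if (nrow(gold) == 0) stop("empty gold standard", call. = FALSE)
  sex <- gold$sex[1]
  if ("sex" %in% names(records)) {
    records <- records[records$sex == sex, , drop = FALSE]
  }
  if (length(unique(records$survey_year)) != 1) {
    stop("baseline expects records of a single (target) year", call. = FALSE)
  }
  records <- records[records$area_id %in% gold$area_id, , drop = FALSE]
  spec <- list(family = "direct", include_race = FALSE, year_effect = "fixed")
  direct_all <- function(data) {
    vapply(gold$area_id, function(a) {
      direct_estimate(data[data$area_id == a, , drop = FALSE], std)
    }, numeric(1))
  }
  rows <- list(score_row(spec, "all", 1L, direct_all(records), gold$estimate, sex))
  for (li in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      sub <- downsample_records(records, levels[li],
                                seed = substream_seed(seed, 500000 + li * 1000 + r))
      rows[[length(rows) + 1]] <-
        score_row(spec, levels[li], r, direct_all(sub), gold$estimate, sex)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_result", "data.frame")
  out
}

#' Rank model specifications by validation performance
#'
#' Ranks specifications by mean CCC over all levels and replicates
#' (descending), breaking ties by mean RMSE (ascending).  Rows flagged as
#' non-converged are excluded from the means and their counts reported.
#' Direct-baseline rows (`family = "direct"`) are reported but not ranked
#' as models.
#'
#' @param result A [run_experiment()] result (optionally rbind-ed with
#'   [score_direct_baseline()] rows).
#' @return data.frame of class `model_ranking`, one row per specification,
#'   ordered best first, with columns `family`, `include_race`,
#'   `year_effect`, `mean_ccc`, `mean_rmse`, `n_rows`, `n_nonconverged`,
#'   `rank`.  The best spec is available via `attr(x, "best")` as a
#'   [model_spec()].
#' @export
rank_models <- function(result) {
  stopifnot(is.data.frame(result), nrow(result) > 0)
  models <- result[result$family != "direct", , drop = FALSE]
  if (all(!models$converged)) stop("no converged model fits to rank", call. = FALSE)
  key <- paste(models$family, models$include_race, models$year_effect)
  agg <- lapply(split(models, key), function(g) {
    ok <- g[g$converged, , drop = FALSE]
    data.frame(family = g$family[1], include_race = g$include_race[1],
               year_effect = g$year_effect[1],
               mean_ccc = if (nrow(ok)) mean(ok$ccc) else NA_real_,
               mean_rmse = if (nrow(ok)) mean(ok$rmse) else NA_real_,
               n_rows = nrow(g), n_nonconverged = sum(!g$converged),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, agg)
  ord <- order(-tab$mean_ccc, tab$mean_rmse)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  best <- model_spec(tab$family[1], include_race = tab$include_race[1],
                     year_effect = tab$year_effect[1])
  attr(tab, "best") <- best
  class(tab) <- c("model_ranking", "data.frame")
  tab
}
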
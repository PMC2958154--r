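#' Spatially averaged random intercept covariate
#'
#' The Geospatial and Full models harness spatial patterns through an area
#' covariate equal to the mean of the estimated county random intercepts of
#' its adjacent neighbors, taken from a first-stage (Naive or Covariate)
#' fit.  Neighbors absent from the first-stage fit contribute 0 (the
#' random-effect prior mean); island areas, which have no defined neighbors,
#' receive 0.
#'
#' @param base A first-stage [fit_glmm()] result.
#' @param graph An [area_graph()].
#' @return Object of class `spatial_covariate`: `values` (named vector over
#'   all graph areas) and `source_spec` (the base model's spec).
#' @export
compute_spatial_covariate <- function(base, graph) {
  stopifnot(inherits(base, "sae_fit"), inherits(graph, "area_graph"))
  if (length(graph$areas) == 0) stop("empty graph", call. = FALSE)
  values <- vapply(graph$areas, function(a) {
    nb <- graph$neighbors[[a]]
    if (length(nb) == 0) return(0)
    v <- base$ranef_mean[nb]
    v[is.na(v)] <- 0
    mean(v)
  }, numeric(1))
  structure(list(values = values, source_spec = base$spec),
            class = "spatial_covariate")
}

#' Fit one of the four model families
#'
#' Naive and Covariate models are single-stage fits.  The Geospatial model
#' first fits the Naive model, derives the [compute_spatial_covariate()]
#' from its estimated random intercepts, then refits with the spatial term;
#' the Full model does the same with a Covariate first stage.  The spatial
#' covariate is computed once and held fixed during the second-stage fit.
#'
#' @inheritParams fit_glmm
#' @param graph An [area_graph()]; required for geospatial/full.
#' @return An [fit_glmm()] result; for two-stage families the returned model
#'   carries the `spatial_covariate` used (and its source spec) in
#'   `$spatial_source`.
#' @export
fit_family <- function(records, spec, counties = NULL, graph = NULL,
                       se_sigma = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (!needs_spatial(spec)) {
    return(fit_glmm(records, spec, counties = counties, se_sigma = se_sigma))
  }
  if (is.null(graph)) stop(sprintf("%s model requires an adjacency graph",
                                   spec$family), call. = FALSE)
  base_family <- if (spec$family == "geospatial") "naive" else "covariate"
  base_spec <- model_spec(base_family, include_race = spec$include_race,
                          year_effect = spec$year_effect, sex = spec$sex,
                          include_age = spec$include_age)
  base <- tryCatch(
    fit_glmm(records, base_spec, counties = counties),
    error = function(e) stop(sprintf("first stage (%s): %s", base_family,
                                     conditionMessage(e)), call. = FALSE))
  sp <- compute_spatial_covariate(base, graph)
  model <- tryCatch(
    fit_glmm(records, spec, counties = counties, spatial_covariate = sp,
             se_sigma = se_sigma),
    error = function(e) stop(sprintf("second stage (%s): %s", spec$family,
                                     conditionMessage(e)), call. = FALSE))
  model$spatial_source <- sp
  model
}

#' Enumerate model specifications
#'
#' Full crossing of the four families with race inclusion and the year
#' effect type gives 16 model specifications per sex; restricting any axis
#' filters the crossing.
#'
#' @param families Subset of the four family names.
#' @param include_race Logical vector of race-inclusion options.
#' @param year_effect Subset of `c("fixed", "random")`.
#' @param sex Optional sex label attached to every spec.
#' @return List of [model_spec()] objects.
#' @examples
#' length(enumerate_specs())  # 16
#' @export
enumerate_specs <- function(families = c("naive", "geospatial",
                                         "covariate", "full"),
                            include_race = c(FALSE, TRUE),
                            year_effect = c("fixed", "random"),
                            sex = NULL) {
  grid <- expand.grid(family = families, include_race = include_race,
                      year_effect = year_effect,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    model_spec(grid$family[i], include_race = grid$include_race[i],
               year_effect = grid$year_effect[i], sex = sex)
  })
}

#' Write a spatial covariate for audit
#'
#' @param sp A [compute_spatial_covariate()] result.
#' @param path CSV path.
#' @export
write_spatial_covariate <- function(sp, path) {
  stopifnot(inherits(sp, "spatial_covariate"))
  utils::write.csv(data.frame(area_id = names(sp$values),
                              value = as.numeric(sp$values)),
                   path, row.names = FALSE)
  invisible(path)
}
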
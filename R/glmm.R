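#' Specify a small-area prevalence model
#'
#' The four model families share a binomial logit mixed-model core with a
#' county random intercept and differ in which area-level information they
#' use: `naive` (demographics only), `geospatial` (adds the spatially
#' averaged random intercept from a first-stage naive fit), `covariate`
#' (adds area covariates Z), and `full` (both, with the spatial covariate
#' derived from a first-stage covariate fit).  Each family can include or
#' exclude an individual race effect and model survey year as fixed
#' categorical contrasts or as a linear trend with independent per-area
#' random slopes.
#'
#' @param family One of `"naive"`, `"geospatial"`, `"covariate"`, `"full"`.
#' @param include_race Include individual race/ethnicity fixed effects?
#' @param year_effect `"fixed"` (categorical contrasts against the earliest
#'   training year) or `"random"` (fixed linear trend plus an independent
#'   per-area random slope on centered year).
#' @param sex Optional sex label; when set, fitting subsets the records.
#' @param include_age Include the age-group fixed effects (default TRUE;
#'   disabling is intended for reduced simulation studies).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("naive", "geospatial", "covariate", "full"),
                       include_race = FALSE,
                       year_effect = c("fixed", "random"),
                       sex = NULL, include_age = TRUE) {
  family <- match.arg(family)
  year_effect <- match.arg(year_effect)
  structure(list(family = family, include_race = isTRUE(include_race),
                 year_effect = year_effect, sex = sex,
                 include_age = isTRUE(include_age)),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  sprintf("%s/race=%s/year=%s%s", x$family,
          if (x$include_race) "yes" else "no", x$year_effect,
          if (is.null(x$sex)) "" else paste0("/", x$sex))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", format(x), "\n")
  invisible(x)
}

needs_covariates <- function(spec) spec$family %in% c("covariate", "full")
needs_spatial <- function(spec) spec$family %in% c("geospatial", "full")

#' Fit a binomial logit mixed model with an area random intercept
#'
#' Maximizes the Laplace-approximated marginal likelihood of the binomial
#' logit model with independent area random intercepts (and, for
#' `year_effect = "random"`, an independent per-area random slope on
#' centered year).  Continuous area covariates are standardized internally
#' for optimizer conditioning and all reported estimates are transformed
#' back to the original covariate scale.  Model fitting is unweighted;
#' poststratification weights enter only the direct estimator.
#'
#' @param records Person records (one sex; if `spec$sex` is set the records
#'   are subset to it).
#' @param spec A [model_spec()].
#' @param counties A [county_table()]; required when the family uses area
#'   covariates.
#' @param spatial_covariate Named numeric vector (area id -> value) or a
#'   `spatial_covariate` object; required when the family uses the spatial
#'   term.  Areas absent from it contribute 0.
#' @param se_sigma Also compute a standard error for the random-intercept SD
#'   from a finite-difference Hessian of the Laplace deviance (slower).
#' @return An object of class `sae_fit`: fixed effects (named vector on the
#'   original covariate scale), their covariance, `sigma_delta`, conditional
#'   means and variances of the area intercepts, log-likelihood, a
#'   convergence flag, and the bookkeeping needed by [predict_linear()].
#' @export
fit_glmm <- function(records, spec, counties = NULL, spatial_covariate = NULL,
                     se_sigma = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  validate_person_records(records)
  if (!is.null(spec$sex) && "sex" %in% names(records)) {
    records <- records[records$sex == spec$sex, , drop = FALSE]
  }
  records <- records[!is.na(records$outcome), , drop = FALSE]
  if (nrow(records) == 0) stop("no records to fit", call. = FALSE)
  if (length(unique(records$area_id)) < 2) {
    stop("random-intercept variance is not identifiable with a single area",
         call. = FALSE)
  }
  if (length(unique(records$outcome)) < 2) {
    stop("outcome is constant; model not identifiable", call. = FALSE)
  }

  d <- data.frame(
    outcome = as.integer(records$outcome),
    area = factor(records$area_id),
    stringsAsFactors = FALSE)
  terms <- character(0)

  if (spec$include_age) {
    d$age_group <- stats::relevel(factor(records$age_group, levels = age_groups()),
                                  ref = age_reference())
    d$age_group <- droplevels(d$age_group)
    terms <- c(terms, "age_group")
  }
  if (spec$include_race) {
    d$race_group <- stats::relevel(factor(records$race_group,
                                          levels = race_groups()),
                                   ref = race_reference())
    d$race_group <- droplevels(d$race_group)
    terms <- c(terms, "race_group")
  }

  year_levels <- sort(unique(records$survey_year))
  year_center <- mean(year_levels)
  if (spec$year_effect == "fixed") {
    if (length(year_levels) > 1) {
      d$year_f <- factor(as.character(records$survey_year),
                         levels = as.character(year_levels))
      terms <- c(terms, "year_f")
    }
  } else {
    d$year_c <- records$survey_year - year_center
    terms <- c(terms, "year_c")
  }

  z_names <- character(0); z_center <- numeric(0); z_scale <- numeric(0)
  z_by_area <- NULL
  if (needs_covariates(spec)) {
    if (is.null(counties)) stop("spec requires a county table", call. = FALSE)
    z_names <- covariate_names(counties)
    idx <- match(records$area_id, counties$covariates$area_id)
    if (anyNA(idx)) {
      stop(sprintf("area '%s' missing from county table",
                   records$area_id[which(is.na(idx))[1]]), call. = FALSE)
    }
    zmat <- as.matrix(counties$covariates[idx, z_names, drop = FALSE])
    z_center <- colMeans(zmat)
    z_scale <- apply(zmat, 2, stats::sd)
    if (any(z_scale == 0)) {
      stop(sprintf("constant area covariate: %s", z_names[z_scale == 0][1]),
           call. = FALSE)
    }
    zs <- sweep(sweep(zmat, 2, z_center), 2, z_scale, "/")
    zcols <- paste0(".z", seq_along(z_names))
    colnames(zs) <- zcols
    d <- cbind(d, zs)
    terms <- c(terms, zcols)
    z_by_area <- counties$covariates[, c("area_id", z_names)]
  }

  sp_values <- NULL
  if (needs_spatial(spec)) {
    if (is.null(spatial_covariate)) stop("spec requires a spatial covariate",
                                         call. = FALSE)
    sp_values <- if (inherits(spatial_covariate, "spatial_covariate")) {
      spatial_covariate$values
    } else spatial_covariate
    v <- sp_values[records$area_id]
    v[is.na(v)] <- 0
    if (stats::sd(v) > 1e-10) {
      d$spatial_ri <- as.numeric(v)
      terms <- c(terms, "spatial_ri")
    } else {
      ## a (numerically) constant spatial covariate -- e.g. the first-stage
      ## random-intercept SD collapsed to zero -- leaves the spatial
      ## coefficient unidentified; the term is dropped
      warning("spatial covariate is constant; spatial term dropped",
              call. = FALSE)
    }
  }

  re_terms <- "(1 | area)"
  if (spec$year_effect == "random") re_terms <- c(re_terms, "(0 + year_c | area)")

  ## collapse identical design rows to binomial cell counts: the marginal
  ## likelihood is unchanged up to a data-only constant (removed again when
  ## the log-likelihood is reported) and fitting is much faster
  key <- do.call(paste, c(d[setdiff(names(d), "outcome")], sep = "\r"))
  first <- !duplicated(key)
  dd <- d[first, setdiff(names(d), "outcome"), drop = FALSE]
  idx <- match(key, key[first])
  dd$.succ <- as.numeric(tapply(d$outcome, idx, sum)[as.character(seq_len(sum(first)))])
  dd$.tot <- as.numeric(tabulate(idx, nbins = sum(first)))
  fml <- stats::as.formula(paste("cbind(.succ, .tot - .succ) ~",
                                 paste(c(terms, re_terms), collapse = " + ")))

  fit <- lme4::glmer(fml, data = dd, family = stats::binomial(),
                     control = lme4::glmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE))

  conv_ok <- isTRUE(fit@optinfo$conv$opt == 0) &&
    length(fit@optinfo$warnings) == 0

  ## fixed effects back on the original covariate scale
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  nm <- names(b)
  p <- length(b)
  A <- diag(p)
  if (length(z_names) > 0) {
    for (k in seq_along(z_names)) {
      j <- match(paste0(".z", k), nm)
      A[j, j] <- 1 / z_scale[k]
      A[1, j] <- A[1, j] - z_center[k] / z_scale[k]
    }
  }
  fe <- as.numeric(A %*% b)
  fe_cov <- A %*% V %*% t(A)

  canon <- nm
  canon[canon == "(Intercept)"] <- "intercept"
  canon <- sub("^age_group", "age:", canon)
  canon <- sub("^race_group", "race:", canon)
  canon <- sub("^year_f", "year:", canon)
  canon[canon == "year_c"] <- "year_trend"
  for (k in seq_along(z_names)) {
    canon[canon == paste0(".z", k)] <- paste0("z:", z_names[k])
  }
  names(fe) <- canon
  dimnames(fe_cov) <- list(canon, canon)

  vc <- lme4::VarCorr(fit)
  sigma_delta <- attr(vc[[1]], "stddev")[[1]]
  sigma_year <- if (spec$year_effect == "random") attr(vc[[2]], "stddev")[[1]] else NULL

  re <- lme4::ranef(fit, condVar = TRUE)[["area"]]
  lv <- rownames(re)
  pv <- attr(re, "postVar")
  if (is.list(pv)) {
    ranef_var <- stats::setNames(as.numeric(pv[[1]][1, 1, ]), lv)
    slope_var <- stats::setNames(as.numeric(pv[[2]][1, 1, ]), lv)
  } else {
    ranef_var <- stats::setNames(as.numeric(pv[1, 1, ]), lv)
    slope_var <- NULL
  }
  ranef_mean <- stats::setNames(re[["(Intercept)"]], lv)
  slope_mean <- if ("year_c" %in% colnames(re)) {
    stats::setNames(re[["year_c"]], lv)
  } else NULL

  sigma_delta_se <- NULL
  if (isTRUE(se_sigma)) {
    devf <- lme4::glmer(fml, data = dd, family = stats::binomial(),
                        devFunOnly = TRUE)
    opt <- c(lme4::getME(fit, "theta"), b)
    H <- fd_hessian(devf, opt)
    info <- H / 2
    cov_all <- try(solve(info), silent = TRUE)
    if (!inherits(cov_all, "try-error") && cov_all[1, 1] > 0) {
      sigma_delta_se <- sqrt(cov_all[1, 1])
    }
  }

  structure(list(
    spec = spec, fixed_effects = fe, fixed_cov = fe_cov,
    sigma_delta = as.numeric(sigma_delta), sigma_delta_se = sigma_delta_se,
    sigma_year = if (is.null(sigma_year)) NULL else as.numeric(sigma_year),
    ranef_mean = ranef_mean, ranef_var = ranef_var,
    slope_mean = slope_mean, slope_var = slope_var,
    ## report the ungrouped (Bernoulli) log-likelihood: subtract the
    ## binomial coefficient constant introduced by cell aggregation
    loglik = as.numeric(stats::logLik(fit)) -
      sum(lchoose(dd$.tot, dd$.succ)),
    converged = conv_ok,
    n_used = nrow(d),
    year_levels = year_levels, year_center = year_center,
    z_names = z_names, z_by_area = z_by_area,
    spatial_values = sp_values), class = "sae_fit")
}

## central-difference Hessian of a scalar function
fd_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  hs <- pmax(abs(x), 1) * h
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + hs[i]
        xm <- x; xm[i] <- x[i] - hs[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / hs[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + hs[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + hs[i]; xpm[j] <- x[j] - hs[j]
        xmp <- x; xmp[i] <- x[i] - hs[i]; xmp[j] <- x[j] + hs[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - hs[c(i, j)]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * hs[i] * hs[j])
      }
    }
  }
  H
}

#' @export
print.sae_fit <- function(x, ...) {
  cat(sprintf("sae_fit [%s]: n = %d, %d areas, sigma_delta = %.4f, logLik = %.2f%s\n",
              format(x$spec), x$n_used, length(x$ranef_mean), x$sigma_delta,
              x$loglik, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param model An [fit_glmm()] result.
#' @return data.frame with columns `term`, `estimate`, `se`, `z`.
#' @export
coef_table <- function(model) {
  stopifnot(inherits(model, "sae_fit"))
  se <- sqrt(diag(model$fixed_cov))
  data.frame(term = names(model$fixed_effects),
             estimate = as.numeric(model$fixed_effects),
             se = se, z = as.numeric(model$fixed_effects) / se,
             row.names = NULL, stringsAsFactors = FALSE)
}

## design rows over demographic cells for one area/year, columns matching
## names(model$fixed_effects).  cells: data.frame(age_group, race_group).
fixed_design <- function(model, cells, area, year,
                         counties = NULL, spatial_covariate = NULL) {
  nm <- names(model$fixed_effects)
  X <- matrix(0, nrow(cells), length(nm), dimnames = list(NULL, nm))
  X[, "intercept"] <- 1
  spec <- model$spec
  if (spec$include_age) {
    check_levels(cells$age_group, age_groups(), "age_group")
    for (i in seq_len(nrow(cells))) {
      a <- cells$age_group[i]
      if (a != age_reference()) {
        col <- paste0("age:", a)
        if (!(col %in% nm)) stop(sprintf("age group '%s' unseen in training data", a),
                                 call. = FALSE)
        X[i, col] <- 1
      }
    }
  }
  if (spec$include_race) {
    check_levels(cells$race_group, race_groups(), "race_group")
    for (i in seq_len(nrow(cells))) {
      r <- cells$race_group[i]
      if (r != race_reference()) {
        col <- paste0("race:", r)
        if (!(col %in% nm)) stop(sprintf("race group '%s' unseen in training data", r),
                                 call. = FALSE)
        X[i, col] <- 1
      }
    }
  }
  if (spec$year_effect == "fixed") {
    if (!(year %in% model$year_levels)) {
      stop(sprintf("year %s unseen in training data", year), call. = FALSE)
    }
    col <- paste0("year:", year)
    if (col %in% nm) X[, col] <- 1
  } else {
    X[, "year_trend"] <- year - model$year_center
  }
  if (length(model$z_names) > 0) {
    zv <- if (!is.null(counties)) county_z(counties, area) else {
      i <- match(area, model$z_by_area$area_id)
      if (is.na(i)) stop(sprintf("no covariates for area '%s'", area), call. = FALSE)
      unlist(model$z_by_area[i, model$z_names, drop = FALSE])
    }
    for (k in model$z_names) X[, paste0("z:", k)] <- as.numeric(zv[[k]])
  }
  if ("spatial_ri" %in% nm) {
    sv <- if (!is.null(spatial_covariate)) {
      v <- if (inherits(spatial_covariate, "spatial_covariate")) {
        spatial_covariate$values
      } else spatial_covariate
      v[area]
    } else model$spatial_values[area]
    X[, "spatial_ri"] <- if (is.null(sv) || is.na(sv)) 0 else as.numeric(sv)
  }
  X
}

## random-effect contribution to the linear predictor for one area/year
ranef_contribution <- function(model, area, year) {
  ri <- model$ranef_mean[area]
  out <- if (is.na(ri)) 0 else as.numeric(ri)
  if (!is.null(model$slope_mean)) {
    sl <- model$slope_mean[area]
    if (!is.na(sl)) out <- out + as.numeric(sl) * (year - model$year_center)
  }
  out
}

#' Linear predictor (log-odds) for one demographic cell
#'
#' Evaluates the fitted fixed effects plus the conditional mean of the
#' area's random effects at one age x race x year cell.  Areas unseen at
#' fit time contribute a random-effect value of 0 (the prior mean).
#'
#' @inheritParams fit_glmm
#' @param model An [fit_glmm()] result.
#' @param area Area id.
#' @param age_group,race_group Demographic labels from the schemas.
#' @param year Survey year.
#' @return Log-odds (numeric scalar).
#' @export
predict_linear <- function(model, area, age_group, race_group, year,
                           counties = NULL, spatial_covariate = NULL) {
  stopifnot(inherits(model, "sae_fit"))
  cells <- data.frame(age_group = age_group, race_group = race_group,
                      stringsAsFactors = FALSE)
  X <- fixed_design(model, cells, area, year, counties, spatial_covariate)
  as.numeric(X %*% model$fixed_effects) + ranef_contribution(model, area, year)
}
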
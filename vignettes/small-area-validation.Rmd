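---
title: "Small area estimation and validation: models, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small area estimation and validation: models, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

National health surveys collect hundreds of thousands of interviews a year,
yet most counties contribute so few respondents that their direct,
design-weighted prevalence estimates are unusable: in a typical year more
than 80% of counties have fewer than 100 respondents. Small area
estimation borrows strength — across survey years, across neighboring
areas, and from area-level covariates — to produce county estimates with
acceptable precision. The hard part is *validation*: in-sample fit and
cross-validation cannot tell you whether a model's estimate for a county
with 30 respondents is close to what a large survey in that county would
have found.

`saeval` implements a complete measurement-and-validation workflow:

1. four families of binomial logit mixed models with a county random
   intercept (Naive, Geospatial, Covariate, Full);
2. a direct, weighted, age-standardized estimator and a gold standard
   built from areas large enough to support it;
3. a downsampling experiment that refits every model on systematically
   impoverished data and scores it against the gold standard with Lin's
   concordance correlation coefficient (CCC) and RMSE;
4. aggregation of person-level predictions to area prevalence with
   empirical credibility regions;
5. a synthetic survey generator with known ground truth, used for all
   testing and calibration.

# The model families

For person $j$ in county $i$ of one sex, the outcome $Y_{ij}$ follows a
binomial logit model

$$\operatorname{logit}\Pr(Y_{ij}=1) = \alpha + \beta_1 \mathrm{AGE}_{ij}
  + \beta_2 \mathrm{RACE}_{ij} + \beta_3 \mathrm{YEAR}_{ij}
  + Z_i\gamma + \beta_4 \bar\delta_i^{\,\mathrm{post}} + \delta_i,$$

with $\delta_i \sim N(0, \sigma_\delta^2)$ independent across counties.
The four families switch terms on and off:

| family     | area covariates $Z_i\gamma$ | spatial term $\beta_4\bar\delta_i^{\,\mathrm{post}}$ |
|------------|------------------------------|------------------------------------------------------|
| naive      | –                            | –                                                    |
| geospatial | –                            | from a first-stage naive fit                         |
| covariate  | yes                          | –                                                    |
| full       | yes                          | from a first-stage covariate fit                     |

Each family can include or exclude individual race effects, and model the
survey year either as categorical contrasts against the earliest training
year or as a linear trend with an independent per-area random slope —
sixteen specifications in all, fit separately by sex.

The spatial covariate $\bar\delta_i^{\,\mathrm{post}}$ is the mean of the
estimated (conditional-mean) random intercepts of county $i$'s adjacency
neighbors, computed once from the first-stage fit and held fixed in the
second stage. Counties with no neighbors (islands) and neighbors absent
from the first stage contribute the random-effect prior mean, zero. If the
first-stage variance collapses to zero the covariate is numerically
constant and the spatial term is dropped with a warning (its direction is
unidentified).

Sexes are modeled separately throughout: age patterns, race gradients and
covariate effects differ by sex, and the framework never pools them.

## Estimation

Models are estimated by maximizing the Laplace-approximated marginal
likelihood (`lme4::glmer`, one quadrature point, `bobyqa` optimization).
Identical person-level design rows are collapsed to binomial cell counts
before fitting; this leaves the likelihood unchanged up to an additive
constant (removed again from the reported log-likelihood, which is always
on the person-record scale) and speeds estimation roughly tenfold. The
test suite verifies the Laplace log-likelihood against an independently
written 51-node adaptive Gauss–Hermite quadrature oracle.

Fitting is unweighted: poststratification weights enter only the direct
estimator. Continuous area covariates are standardized internally for
optimizer conditioning and estimates are reported on the original scale.
Model convergence is taken from the optimizer's return status and any
fitting warnings; non-converged validation fits are flagged and excluded
from summary means, with counts reported, never dropped silently.

## Direct estimation and the gold standard

The direct estimator for one area and sex proceeds in a fixed order:
weight-weighted outcome means within survey-year × age cells, equal-weight
averaging over years within age group, then age standardization with the
standard population renormalized over the age groups present. The
renormalization (rather than imputing zero prevalence for empty age
groups) avoids a deterministic downward bias in sparse areas; gold-standard
areas are large, so it rarely binds. Race is not a standardization axis
for the gold standard.

The gold standard keeps the area × sex cells whose record count exceeds a
threshold (default 900) in *both* of two pooled year windows. Which pooled
window the estimate itself is computed on is genuinely ambiguous in the
tradition this follows, so it is a parameter (`estimate_window`,
defaulting to the second window).

## Aggregation and uncertainty

Person-level predictions are aggregated to area prevalence by evaluating
the inverse-logit linear predictor in every age × race cell (age-only for
race-free models) and weighting by the standard age distribution times the
area's race composition, renormalized to one. The built-in standard
population approximates the 2000 US age distribution of persons 30 and
older; any distribution over the ten age groups can be substituted.

Credibility regions draw fixed effects from a multivariate normal with the
fitted mean and covariance, and the area's random effects from normals
with their conditional means and variances; each draw is aggregated and
the empirical 2.5%/97.5% order statistics (ranks
$\lceil 0.025d \rceil$, $\lceil 0.975d \rceil$ of $d$ draws) are
reported. Two approximations are deliberate and documented: fixed effects
and random effects are sampled independently (the Laplace fit does not
supply their cross-covariance), and $\sigma_\delta$ is held fixed across
draws. Simulation shows empirical coverage at the nominal 95% level under
a correctly specified generative model (the test suite checks coverage
over 100 synthetic datasets).

## The validation experiment

Records from gold-standard areas are downsampled with replacement to a
fixed number of observations per county-year (default levels 100, 50, 10,
ten replicates each), each model family is refit on the reduced data, the
target year's standardized prevalence is predicted for every gold area,
and CCC and RMSE are computed against the gold standard; one additional
row per specification uses the full data. The single-year direct
estimator is scored through the same machinery as a baseline.
Specifications are ranked by mean CCC over all levels and replicates
(descending), ties broken by mean RMSE (ascending); aggregation across
levels with equal weight is a documented, configurable choice, and
per-replicate rows are always retained so other summaries are
recoverable.

# The synthetic generator as a study design

The generator is first-class, tested code; its defaults are the study
conditions under which the framework is exercised, chosen once to mimic
the regime of multi-year US county telephone-survey data on diagnosed
adult diabetes:

* baseline prevalence near 8% (`alpha = -2.44`), age effects from −1.6
  (ages 30–34) to about +0.85 (70–74) on the logit scale, minority race
  effects of 0.46–0.84, a secular trend of +0.04 logits per year;
* two area covariates jointly worth 0.2 SD on the logit scale, correlated
  0.3 with the residual intercept field (the joint distribution of real
  county covariates is unknowable from published summaries; the single
  correlation knob is a flagged modeling choice);
* a residual county intercept SD of 0.10 — the scale such surveys report
  after covariate adjustment — and one neighbor-mixing pass
  with weight 0.4, emulating contiguity correlation without a full CAR
  model — the mixed field is rescaled back to the target SD so
  `sigma_delta` keeps its meaning;
* county-year sample sizes from a gamma–Poisson law with a *persistent*
  county size factor (dispersion 2), so the same few counties are large
  in every year and most county-years stay under 20 respondents;
* mean-one positive weights with coefficient of variation 0.5 — a weight
  *magnitude* model only; no raking, telephone-frame selection or
  nonresponse is emulated, so tests say nothing about weight-induced
  bias in real surveys.

County age × race compositions vary by Dirichlet draws around national
margins; the true standardized prevalence of every county is computed by
exact aggregation of inverse-logit cell probabilities at the prediction
year, giving every experiment a known target.

# Problem sizes used in the checks

The statistical checks run at sizes chosen to make each property sharply
testable while staying cheap enough to run routinely: parameter recovery
and spatial detection use 100 simulation replicates (200 areas × 150
records, and 150 counties × 3 years × 50 respondents, respectively);
the validation-pattern check uses about 60 gold areas with 5 replicates
per level; coverage uses 100 datasets of 48 counties with 500 parameter
draws. These are stated as the package's own study sizes.

# Numerical and design notes

* **Two-stage inference is approximate.** The spatial covariate is built
  from estimated random intercepts of the same field the second stage
  models, and its estimation error is ignored thereafter — exactly the
  construction this framework follows. Simulation shows the Wald
  statistic of $\beta_4$ is mildly overdispersed under spatial
  independence (null SD ≈ 1.2–1.5 rather than 1), so two-sided tests on
  $\beta_4$ are anti-conservative. The package treats spatial detection
  as the directional claim actually made (a significantly *positive*
  $\beta_4$), and users should read $\beta_4$'s nominal significance
  with this caveat.
* **Degenerate fits.** A first-stage variance of zero drops the spatial
  term (see above); a single area or a constant outcome is a hard error;
  complete-separation blowups surface as non-converged flags in the
  validation tables.
* **Determinism.** All randomness flows from one master seed through
  fixed per-stage substreams; the full pipeline is byte-reproducible for
  a fixed configuration and seed.
* **Random year slopes** use a fixed linear trend plus an independent
  per-area slope on centered year (no intercept–slope covariance). A
  mean-zero slope alone would leave the secular trend unmodeled.
* **`include_age`** exists on `model_spec()` so reduced simulation
  studies can fit exactly the generating model; applied analyses keep it
  `TRUE`.

# What passing tests do and do not show

The synthetic world is generated by the same family of models being
fitted (plus controlled misspecifications: race composition variation not
in $Z$, covariate–intercept correlation). Passing checks therefore show
internal coherence, correct arithmetic against independent oracles, and
the qualitative validity ordering — covariate-informed families dominate
pure measurement models as information shrinks, and every family
dominates single-year direct estimates. They cannot show robustness to
real-survey features the generator does not emulate: informative
weighting, frame undercoverage, self-report bias, or spatial structure
unlike contiguity mixing.
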
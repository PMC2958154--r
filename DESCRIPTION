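Package: saeval
Title: Small Area Estimation and Validation for Survey Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for small area estimation of disease prevalence from
    multi-year survey microdata, and for validating competing estimation
    strategies against a direct gold standard.  Implements four families of
    binomial logit mixed models with county random intercepts (Naive,
    Geospatial, Covariate, Full), a two-stage spatially averaged random
    intercept covariate, weighted age-standardized direct estimation, a
    downsampling validation experiment scored by Lin's concordance
    correlation coefficient and RMSE, demographic aggregation of person-level
    predictions to area prevalence, and empirical credibility regions from
    parameter draws.  Includes a synthetic survey-data generator with known
    ground truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
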
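Package: lipidprs
Title: Longitudinal Polygenic Prediction of Lipid Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating genomic risk models of
    longitudinal lipid levels (HDL-C, LDL-C, total cholesterol,
    triglycerides). Implements random-intercept linear mixed models with a
    sigmoidal (sine) age transform, published-weight polygenic risk scores
    with effect-allele harmonisation and largest-study deduplication,
    within-cohort leave-one-subject-out marker-effect scores, Bayesian lasso
    and Bayesian ridge whole-genome regression via Gibbs sampling, and a
    leave-one-subject-out cross-validation framework reporting predictive
    R-squared (squared Pearson correlation between observed and predicted
    values) with cluster-bootstrap confidence intervals, score significance
    tests, and age-window analyses. A longitudinal cohort simulator with a
    known generative truth supports end-to-end testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
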
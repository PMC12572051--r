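Package: shockdml
Title: Health-Shock Effects on Health Behaviors via Double/Debiased Machine Learning
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how sudden drops in physical and mental
    component summary scores (PCS/MCS) affect binary health behaviors
    (not smoking, healthy diet, doing sports) in long individual-by-wave
    panels. Provides a synthetic panel generator with known ground truth,
    the relative-drop shock definition, timing-aware estimation-sample
    construction (including placebo and full-history variants and attrition
    outcomes), cross-fitted nuisance estimation with random forests or
    L1-penalized logistic regression, the augmented inverse-probability
    weighting (AIPW) average treatment effect estimator with repeated
    sample splitting and median aggregation, and a diagnostic suite
    (covariate balance, threshold sensitivity, placebo tests, attrition
    analysis, effect-heterogeneity screening).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
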
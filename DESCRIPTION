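Package: ipwmsm
Title: Per-Protocol Target Trial Emulation with Inverse Probability
    Weighted Marginal Structural Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Emulates a per-protocol randomized comparison of two
    treatment regimens from longitudinal dispensing, enrollment,
    event and covariate tables. Builds the discrete-time (90-day)
    person-quarter analytic dataset under a drug-supply exposure rule
    with cause-specific right censoring, estimates treatment and
    censoring propensity scores by pooled logistic regression or a
    discrete Super Learner over candidate adjustment sets, assembles
    stabilized and truncated inverse probability weights, and fits
    saturated and proportional-hazards logistic marginal structural
    models for counterfactual hazards. Reports hazard ratios, survival
    curves, risk differences at 1 and 2 years, an area-between-curves
    test and participant-level bootstrap confidence intervals. Includes
    a synthetic longitudinal cohort generator with a Monte-Carlo
    counterfactual-risk oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
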
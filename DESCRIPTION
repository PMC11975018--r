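Package: mlbpsp
Title: Multidimensional Longitudinal Biopsychosocial Phenotyping
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-step pipeline for identifying multidimensional
    longitudinal biopsychosocial phenotypes in clinical cohorts. Step one
    fits per-feature linear mixed-effects models with quadratic-time random
    slopes and extracts empirical-Bayes random effects per participant;
    step two standardizes and compresses the random-effect matrix with
    principal components analysis and clusters participants with k-means,
    selecting the number of clusters by the elbow method. Downstream tools
    characterize the phenotypes (ANOVA / chi-square baseline comparisons,
    longitudinal outcome mixed models with Benjamini-Hochberg-adjusted
    contrasts), model baseline predictors of phenotype membership with
    univariable and multivariable multinomial logistic regression and Wald
    inference, and classify phenotypes from baseline scores with a random
    forest and binary logistic regression under cross-validation. A
    synthetic cohort generator with configurable trajectories, missingness
    and baseline covariates makes every stage testable without restricted
    study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    clue,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
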
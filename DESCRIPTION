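Package: tabsurv
Title: Deep and Penalized Cox Survival Modelling for Heterogeneous Tabular Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits and compares five right-censored survival models on mixed-type
    tabular cohort data: three neural networks (feedforward, densely connected,
    and a TabTransformer variant with a linear Cox output node) trained with a
    negative log Breslow-approximation Cox partial-likelihood loss, an
    elastic-net penalized Cox model, and a stability-selected Cox model pooled
    across multiply imputed datasets with Rubin's rules. Includes chained-equations
    multiple imputation with quickpred-style predictor selection, cohort-style
    preprocessing (dichotomization, log2 transforms, training-split min-max
    normalization, variance-inflation-factor pruning, Schoenfeld proportional-hazards
    diagnostics), nested cross-validation, inverse-probability-of-censoring-weighted
    concordance, time-dependent ROC metrics with bootstrap confidence intervals,
    and a seeded generator of synthetic ageing-cohort survival data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
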
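Package: irnet
Title: Insulin-Resistance Surrogate Markers via Discrete Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing insulin-resistance surrogate markers
    (HOMA-IR, the triglyceride-glucose index, and the triglyceride to HDL
    cholesterol ratio) against diabetes and dyslipidemia in complex-survey
    cohorts such as KNHANES. Implements the full analysis pipeline: clinical
    index derivation and categorical cut-offs, exclusion cascades,
    survey-weighted descriptive statistics with second-order Rao-Scott
    chi-square tests, weighted mutual information and ROC/AUC, discrete
    Bayesian-network structure learning by AIC hill-climbing with bootstrap
    arc-strength model averaging, Markov blankets and d-separation,
    conditional-probability queries by exact enumeration and likelihood
    weighting, and a seeded synthetic cohort generator with a known
    ground-truth network for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
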
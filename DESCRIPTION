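Package: himasurv
Title: Propensity-Score-Adjusted High-Dimensional Mediation Analysis for
    Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Selects and tests DNA-methylation-style mediators of a binary
    exposure on a right-censored survival outcome when the number of
    candidate mediators far exceeds the sample size and exposure is not
    randomised. Confounding is adjusted through an estimated propensity
    score used as a single covariate; candidate mediators are reduced by
    sure independence screening, selected by a minimax-concave-penalty
    (MCP) Cox proportional-hazards fit with coordinate descent, and tested
    by Sobel and joint-significance tests with Bonferroni correction over
    the selected set. Includes the simulation data-generating process used
    to benchmark mediator-selection accuracy and indirect-effect
    estimation, comparison modes that adjust all confounders directly or
    ignore them, and delimited-text input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
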
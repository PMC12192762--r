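Package: entsdm
Title: Maximum-Entropy Species Distribution Modelling with Tuning,
    Scenario Projection and Range-Shift Accounting
Version: 0.1.0
Authors@R: person("entsdm", "maintainers", role = c("aut", "cre"),
    email = "maintainers@entsdm.invalid")
Description: A self-contained maximum-entropy (MaxEnt-style)
    presence-background species distribution modelling pipeline: ESRI
    ASCII grid input/output, spatial thinning of occurrence records,
    Pearson collinearity pruning of bioclimatic layers, L1-regularized
    Gibbs model fitting over linear, quadratic, product, hinge and
    threshold features, ENMeval-style tuning of regularization
    multipliers and feature-class combinations under AICc and omission
    criteria, replicate-based evaluation (AUC, TSS, omission), variable
    importance (percent contribution, permutation, jackknife), response
    curves, suitability classification, class-area change accounting
    under future climate scenarios, and range-centroid shift analysis.
    Includes a synthetic-landscape generator with known truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
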
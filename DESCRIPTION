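Package: plasmasig
Title: Plasma Proteomic Signature Discovery for Duration-of-Response Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery of blood-based prognostic protein signatures from
    small targeted-proteomics (MRM-MS) cohorts stratified by duration of
    treatment response. Implements per-protein differential expression with
    a direction-consistent top-k signature rule, single-sample gene-set
    enrichment (ssGSEA) patient scoring, a four-learner feature-importance
    ensemble (gradient-boosted trees, lasso, ridge, elastic net) with a
    survivor-function rate-change importance cutoff, and an exhaustive
    1-3 protein panel search using Firth bias-reduced logistic regression
    with optimism-corrected cross-validated AUC and a permutation null.
    Includes a synthetic-cohort generator with planted effects for
    end-to-end validation, and Kaplan-Meier median-split reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    xgboost,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
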
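Package: bayesboost
Title: Detecting and Correcting Under-Represented Patient Cohorts with
    Bayesian-Network Oversampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects under-represented patient cohorts in tabular health
    data through classifier-uncertainty analysis and corrects them by
    evidence-conditioned oversampling from a discrete Bayesian network
    (the BayesBoost procedure). Includes a controlled bias-injection
    simulator built on the same network machinery, SMOTE, AdaSyn and a
    simplified Fair-SMOTE baseline for comparison, an evaluation harness
    with t-test confidence intervals and group-fairness diagnostics, and
    seeded generators of primary-care-like synthetic datasets with known
    dependence structure for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
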
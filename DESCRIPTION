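Package: fairaudit
Title: Provenance-Based Fairness Auditing for Clinical Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for auditing group fairness in clinical risk prediction
    models through decision provenance. Simulates patient cohorts with a
    controllable injected gender bias in the readmission-generating process,
    fits logistic-regression and random-forest risk models that log the
    mechanism of every prediction (per-feature logit contributions, per-tree
    decision paths and votes, impurity importances), computes group fairness
    statistics (selection rates, demographic parity difference, equal
    opportunity difference) with permutation significance tests,
    cross-validated stability estimates, counterfactual attribute-flip
    analyses and bias-magnitude sensitivity sweeps, and assembles results
    into a tamper-evident, hash-chained AI Fairness Provenance Record (AFPR)
    with schema validation and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    ranger,
    pROC,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
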
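Package: ssitriage
Title: Multimodal Risk Modelling and Triage Pathway Simulation for
    Remote Surgical Wound Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying automated assessment in remote postoperative
    wound monitoring for surgical-site infection (SSI). Provides a synthetic
    cohort generator emulating patient-reported outcome measures (PROMs),
    clinician triage labels, confirmed-SSI outcomes and synthetic wound
    images; a compact neural-network engine for the PROMs multilayer
    perceptron, a small convolutional image classifier with class-activation
    heatmaps, and probability-level late fusion; grouped stratified
    splitting and discrimination metrics; and a triage-pathway simulator
    that converts model probabilities into routing decisions, diagnostic
    accuracy, failure rates, staff-hours and annual full-time-equivalent
    workload, with threshold sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2
Config/testthat/edition: 3
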
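Package: prostasim
Title: Agent-Based Simulation of Prostate Cancer Onset and Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional, on-grid, stochastic agent-based model of
    prostate cancer onset and progression in a prostatic acinus. Ships two
    simulators: a minimal tumor-maintenance model (tumor cells and cancer
    stem cells randomly seeded on a lattice) and a full nine-agent acinus
    model with luminal, basal, stem, tumor, fibroblast, CAF and M1/M2
    macrophage agents interacting across a basement membrane and
    extracellular matrix. Includes stage detection and batch summaries,
    one-at-a-time parameter sensitivity analysis, particle-swarm-optimization
    calibration of cell parameters against growth and apoptosis curves, an
    eight-group in-silico patient cohort builder with a median-vote patient
    classifier, and a command-line interface for reproducible batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
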
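Package: netreconfig
Title: Time-Varying Brain Network Reconfiguration from Sliding-Window
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how brain regions reorganise across functional
    networks over the course of a resting-state fMRI scan.  Builds
    sliding-window connectivity matrices from parcellated BOLD time
    series (absolute Fisher r-to-z transformed Pearson correlations),
    assigns regions to canonical resting-state networks per window via
    an iterative reassignment procedure seeded from literature-based
    labels, and derives node-level reconfiguration metrics (promiscuity,
    flexibility, cohesion, disjointedness) with global and per-network
    summaries.  Includes Fourier phase-randomization surrogate null
    models, covariate-adjusted group statistics (Bonferroni-corrected
    correlations, ANCOVA, hierarchical ENTER regression), and a fully
    seeded synthetic-data generator with planted community-switching
    events for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tools
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
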
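Package: PlanTopo
Title: Resting-State Network Topology and Tower of London Planning
    Performance
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Relates resting-state functional brain-network topology to
    planning performance on the Tower of London task. Builds per-subject
    functional connectivity matrices by band-averaged complex Morlet
    wavelet coherence (0.06-0.12 Hz), computes weighted graph measures
    (global and subnetwork efficiency and clustering, within- and
    between-network mean connectivity), applies motion and behavioral
    quality control with node harmonization, and fits bootstrapped
    hierarchical regression models with bias-corrected and accelerated
    (BCa) confidence intervals, inversion-based bootstrap P values and
    Benjamini-Hochberg false-discovery-rate control. Includes an exact
    three-bead Tower of London state-space solver and a synthetic-cohort
    generator with planted age and network-integration effects so the
    whole pipeline is testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
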
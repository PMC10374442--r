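Package: syntroscreen
Title: Hit Calling and Population Dynamics for Syntrophic Yeast Coculture Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput growth-complementation
    screens that detect spontaneously syntrophic pairs of auxotrophic yeast
    strains from microplate OD600 readings. Provides plate-reader parsing,
    blank correction, robust replicate-spread and contamination filters,
    positional-bias detection, Z-factor activity-range gating, and hit
    calling by fold difference against the fittest constituent monoculture
    with two-sided Welch tests and Benjamini-Hochberg correction. Also
    estimates coculture subpopulation proportions over time from
    dual-fluorophore readouts via per-strain calibration curves, quantifies
    ratio stability across serial passages, and ships a synthetic-data
    generator with planted ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
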
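Package: cytofect
Title: Quantitative Flow-Cytometric Analysis of Transfection Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify transfection efficiency from flow-cytometry
    event data using two independent single-cell readouts: uptake of a
    fluorochrome-labeled nucleic acid plasmid and expression of the encoded
    protein. Implements an automated gating hierarchy (doublet
    discrimination, intact-cell gating, dye- or scatter-based viability),
    control-based positivity thresholds and blank-corrected median
    fluorescence (dMFI), MESF bead calibration to standardize fluorescence
    down to plasmid copies per cell, toxicity quantification, and
    study-level analyses (time-course peak finding, inter-assay coefficients
    of variation, control normalization, nonparametric comparisons, Spearman
    correlations). Ships a seeded synthetic cytometry simulator with ground
    truth labels, FCS 3.0/3.1 and CSV event I/O, and an end-to-end pipeline
    driven by a YAML/JSON configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
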
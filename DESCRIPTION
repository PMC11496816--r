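Package: pcctomo
Title: Phase-Contrast CT Simulation and Volumetric Morphometry of Thymic
    Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for propagation-based
    phase-contrast computed tomography (PC-CT) of the developing human
    thymus. Generates labelled 3D thymus phantoms (cortex, medulla,
    Hassall's bodies, interlobular gaps), simulates Fresnel free-space
    propagation projections under a parallel-beam synchrotron geometry,
    performs Paganin single-distance phase retrieval with automated
    delta/beta selection, reconstructs volumes by filtered backprojection
    including the extended field-of-view half-acquisition stitch,
    propagates sparse slice annotations to full volumes with a
    random-forest pixel classifier, detects Hassall's bodies by robust
    intensity rules, and computes normalised volumetric compartment
    contents with exact two-sided Wilcoxon rank-sum group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    ranger,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
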
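Package: hciscreen
Title: High-Content Imaging Analysis for Cell-Surface Ligand Binding Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-content imaging screens that detect
    low-affinity extracellular ligand-receptor interactions on transiently
    transfected cells in 384-well plates. Two-channel fluorescence fields
    (nuclei and ligand) are background-corrected, nuclei are segmented as
    primary objects, circular per-cell regions of interest are measured
    against a fixed intensity threshold, and cells are classified as
    ligand-bound by a response limit to give the percentage of responding
    cells per well. Plate-level tools handle the 384-well layout with edge
    exclusion and control columns, control-based threshold calibration,
    nuclei-count quality control, heatmaps and rank-ordered hit calling, and
    a beta-lactamase activity utility normalizes probe concentrations. A
    seeded synthetic image generator produces two-channel fields with known
    per-cell ground truth so the whole pipeline is testable without an
    instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
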
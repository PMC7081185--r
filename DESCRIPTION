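Package: vsimri
Title: Dual-Contrast Vessel Size Imaging: Simulation, Relaxometry and
    Vascular Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for susceptibility-contrast vessel size imaging (VSI) of
    the brain microvasculature and angiographic macrovascular morphometry.
    Includes a Monte Carlo finite-perturber simulator of contrast-induced
    transverse relaxation (delta-R2 and delta-R2*) over synthetic
    random-cylinder vascular substrates; voxel-wise mono-exponential
    relaxometry (ADC, R2, R2*) with VSI, Q and microvessel density (MVD)
    mapping; maximal-inscribed-sphere local thickness for vessel diameter
    quantification on angiographic volumes; ADC-threshold ischemic-edema
    classification with ROI statistics; and seeded generators of
    multi-contrast brain phantoms and tubular vascular phantoms with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    ggplot2
Config/testthat/edition: 3
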
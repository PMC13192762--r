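Package: orgscale
Title: Organelle Scaling Analysis with Synthetic 3D Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how organelle content scales with cell volume in
    budding yeast-like cells spanning a ~100-fold volume range. Provides a
    ground-truthed synthetic-data generator (tabular populations, rendered
    two-channel 3D stacks, single-cell growth traces, analytic
    spherical-vacuole geometry tables), an image-quantification pipeline
    (cell segmentation from a cytosolic marker, background subtraction,
    organelle segmentation, vacuole volumetry with sub-resolution exclusion,
    cortical glancing-slice densitometry), a statistical layer for log-log
    power-law fits, density-trend tests, small-versus-large contrasts and
    exponential growth fitting, and a reproducible end-to-end runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
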
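Package: segbench3d
Title: Ground-Truth Construction and Benchmarking for 3D Microscopy
    Segmentation
Version: 0.1.0
Authors@R:
    person("Segbench", "Developers", email = "segbench@example.org",
           role = c("aut", "cre"))
Description: Threshold-based construction of labelled ground-truth stacks
    from calibrated grayscale confocal image stacks (slice-wise wand ROIs,
    seeded 3D connected-threshold region growing, dual-threshold depth
    compensation) and quantitative benchmarking of a machine segmentation
    against a ground truth: pixel-level precision, recall and F-measure per
    stack and per slice, and object-level one-to-one, split, merged, false
    positive and false negative correspondence.  Includes six classical
    histogram auto-threshold algorithms (Otsu, IsoData, Li, Huang, Yen,
    Renyi), connected-component labelling with volumetry, a calibrated
    phantom generator emulating fluorescently labelled nuclei, and a
    subcommand command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
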
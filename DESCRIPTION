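Package: lithogate
Title: Stone Tracking and Firing-Gate Analysis for Shockwave Lithotripsy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for ultrasound-guided
    extracorporeal shockwave lithotripsy (ESWL) gating. Generates
    synthetic B-mode-like frame sequences of a respirating kidney stone
    with exact ground truth, trains a compact U-Net stone/kidney
    segmenter with patient-based cross-validation and early stopping,
    converts predicted masks into firing decisions via a focal-zone
    overlap rule, and evaluates the result with confusion-matrix
    diagnostics, treatment-efficiency estimates, bias-corrected and
    accelerated (BCa) bootstrap hit-rate intervals, and a chi-square
    pooling test for hit-rate homogeneity across patients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    e1071,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    boot,
    jsonlite,
    optparse
Config/testthat/edition: 3
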
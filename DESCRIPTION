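Package: needletrace
Title: Attention-Gated 3D U-Net Digitization of Interstitial Needles in HDR Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end automatic digitization of interstitial needles for
    high-dose-rate (HDR) brachytherapy planning on CT-like volumes. Provides a
    seeded synthetic needle-phantom generator with analytic ground truth, a 3D
    U-Net segmentation network with optional additive attention gates and group
    normalization trained with a soft Dice loss (implemented natively with
    RcppArmadillo GEMM convolutions and hand-derived backpropagation), per-needle
    centerline extraction with polynomial trajectory fitting and dwell-position
    sampling, the standard geometric accuracy metrics (Dice, Jaccard, Hausdorff
    distance, tip and shaft errors) with paired significance testing, and a
    TG-43 point-source dose engine with cumulative DVH metrics (D90, D100, D2cc)
    for manual-versus-automatic plan comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
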
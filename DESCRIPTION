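Package: octga
Title: Predicting Geographic Atrophy from Baseline OCT with Deconvolutional
    Feature Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-modal longitudinal pipeline for dry age-related macular
    degeneration: registers follow-up fundus-autofluorescence (FAF) geographic
    atrophy annotations into baseline OCT coordinates with a keypoint
    homography, extrudes them into per-B-scan ground truth between the ILM and
    choroid-sclera boundaries, trains a square-filter U-Net with a combined
    Dice and binary cross-entropy loss to segment future atrophy from baseline
    B-scans, and inverts the trained network block by block with shared-weight
    transposed convolutions and max-pooling switches to reconstruct the
    baseline lesions (druse clusters, hyper-reflective foci, subretinal
    drusenoid deposits) that drive each prediction. A seeded retinal phantom
    generator provides fully synthetic OCT/FAF case sets with known lesions,
    layer boundaries, planar misalignment and conversion ground truth, so the
    whole pipeline is testable end to end, together with multi-class Otsu
    binarization, confusion-matrix metrics and k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
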
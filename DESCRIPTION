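Package: canopyseg
Title: Weakly Supervised Segmentation of Stress Lesions on Dense Plant Canopies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Localizes small stress lesions (such as lettuce tip-burn) on
    large, dense plant-canopy images using only image-level class labels.
    Implements hard-stride patch splitting, patch classification behind a
    pluggable contract, reconstruction of an overlap-averaged attention map,
    refinement of patch pseudo-labels with a graph convolutional network
    built on Jensen-Shannon divergence colour-histogram graphs, full-canopy
    mask reconstruction with tray/cell region attribution, a patch-based
    Dice/IoU evaluation harness with ablation variants, single-leaf
    background removal for class-folder leaf datasets, and a deterministic
    synthetic canopy/leaf generator with exact ground-truth masks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
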
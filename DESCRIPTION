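Package: pollenseg
Title: Weakly Supervised Segmentation and Classification of Pollen Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Collaborative-learning pipeline for single-particle scanning
    electron microscopy micrographs of airborne pollen. Pseudo segmentation
    masks are extracted without pixel annotation by Canny edge detection,
    morphological contour cleanup, area-based impurity filtering and flood
    filling; gradient-weighted class activation maps (Grad-CAM) computed from
    an image-level classifier refine the masks by maximum-intersection
    component selection; and a mask-guided classifier and a U-Net-style
    segmenter are trained in alternating rounds so each task improves the
    other's supervision. Includes a seeded synthetic micrograph generator
    with ground-truth masks, classification metrics
    (precision/recall/specificity/F1), segmentation metrics (mean IoU, mean
    pixel accuracy), broom-style tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rlang
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
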
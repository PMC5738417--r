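Package: nucmorph
Title: Nuclear Morphometry and Chromatin Condensation Analysis for
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end single-cell nuclear morphometry for DAPI-stained
    wide-field fluorescence images. Segments nuclei by marker-based
    watershed with overexposure, edge-blur and size quality filters,
    quantifies chromatin condensation as the heterochromatin to
    euchromatin intensity ratio, extracts shape and texture feature
    vectors (local binary patterns, parameter-free threshold adjacency
    statistics, Zernike moments), and classifies nuclei with linear
    baselines (with feature-ablation tables) and a VGG-style
    convolutional network, including a patch-level interpretable
    classifier with decision and filter heat-maps. A seeded synthetic
    image generator with ground-truth masks makes every stage testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    rhdf5,
    Rtsne,
    glmnet,
    e1071,
    ranger,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    tiff
Config/testthat/edition: 3
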
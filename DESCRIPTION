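Package: melmap
Title: Patch-Based Melanoma Recognition and Probability Mapping for Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing malignant melanoma in whole-slide histopathology
    images by sliding-window tiling, patch-wise classification with a residual
    network augmented by deformable convolution, squeeze-excitation channel
    attention and multi-scale feature fusion, and aggregation of patch predictions
    into a slide-level probability map with a thresholded mosaic mask and lesion
    regions. Includes a self-contained CNN implementation (forward and backward
    passes with compiled sampling kernels), an SGD-with-momentum training loop,
    and a seeded generator of H&E-like synthetic slides with ground-truth masks
    so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
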
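Package: dryshrink
Title: Image-Based Shrinkage Extraction and Moisture-Ratio Modeling for
    Food Drying
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to monitor food drying from top-view images. Extracts
    projected-area shrinkage of drying slices with a clustering-threshold
    segmentation pipeline (grayscale conversion, intermeans or Otsu
    thresholding, hole filling, largest-particle filtering), models the
    dimensionless moisture ratio as a low-order polynomial in shrinkage,
    and fits the polynomial by minimizing the maximum-likelihood fitness
    function (the mean squared residual) with a differential-evolution
    style population algorithm. Includes fit-quality metrics with
    adjusted R-squared model-order selection, a synthetic fixture
    generator producing drying curves and rendered multi-disk image
    stacks with ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
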
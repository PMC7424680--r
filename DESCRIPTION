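Package: dapdr
Title: Developmental Normalization and Rosette Image Analysis for Plant Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated developmental-stage normalization of time-series plant
    phenotyping measurements (DAPD): exponential leaf-number trend fitting, a
    population mean trend, per-plant integer-day shift selection by mean squared
    deviation, and a whole-day area adjustment, so that plants are compared at
    equal developmental stages rather than equal days after sowing. Includes the
    top-view rosette segmentation pipeline that feeds it (excess-green index,
    Otsu thresholding, CLAHE, hue-histogram clustering with Savitzky-Golay
    smoothing, K-means background removal, random-gamma consensus and
    interpolation-based over-segmentation repair), marker-controlled watershed
    leaf counting, segmentation accuracy metrics (precision, recall, Jaccard,
    Dice), dispersion curves, robust outlier detection, and seeded synthetic
    generators for rosette images and plant-population growth series with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
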
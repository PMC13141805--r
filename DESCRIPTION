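Package: steatr
Title: Feature-Based Quantification of Macrovesicular Steatosis in Liver Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies macrovesicular steatosis (large lipid vacuoles) on
    hematoxylin-eosin stained liver histology images using stain-agnostic
    grayscale processing and interpretable region shape descriptors. Provides
    tissue masking with artifact suppression (tears, folds, coverslip glare),
    brightness-adaptive vacuole candidate detection, shape-based classification
    (area, roundness, circularity, compactness, convexity, anisometry),
    area-fraction quantification with ordinal grading, rater-agreement
    statistics (quadratically weighted Cohen's kappa, correlation, RMSE,
    Bland-Altman, tolerance rates), and a seeded synthetic-slide generator
    with ground-truth masks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
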
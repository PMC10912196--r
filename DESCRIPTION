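Package: latentyield
Title: Latent Growth-Curve Phenotypes and Ensemble Yield Prediction for
    UAV-Phenotyped Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for plot-level yield prediction in field
    breeding trials phenotyped by repeated UAV imagery. Extracts canopy
    traits (cover, height, volume, excess-green) from plot-level RGB and
    elevation tiles by HSV segmentation, fits logistic and Gompertz growth
    curves to each plot's trait time series, derives fourteen latent
    phenotypes from the fitted curves and their growth-rate (first
    derivative) curves, prunes them by variance inflation factor and
    recursive feature elimination, and cross-validates random-forest and
    gradient-boosting yield models by Monte-Carlo and k-fold protocols.
    Includes a synthetic trial generator with known ground truth, and
    breeding-oriented evaluation: per-flight trait-yield correlations,
    repeatability from variance components, and percentile yield-bin
    confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    ranger,
    stats,
    tiff,
    utils,
    xgboost
Suggests:
    ggplot2,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
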
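Package: lulcfuse
Title: Ensemble Land-Cover Classification with Posterior Fusion and
    Pixel-Level Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps land use / land cover (LULC) from multi-temporal
    satellite composites by training several probabilistic classifiers
    (random forest, support vector machine, weighted k-nearest
    neighbours, neural network, naive Bayes) on seasonal reflectance
    statistics, vegetation-index phenology metrics and terrain
    derivatives, then fusing their outputs by majority vote or by
    Bayesian averaging of class-membership probabilities. Provides
    pixel-level uncertainty layers (vote counts, maximum fused
    probability), confusion-matrix accuracy assessment with producer's
    and user's accuracy and Cohen's kappa, training-sample-size
    sensitivity analysis, and post-classification change detection via
    land-conversion matrices. Includes a seeded generator of synthetic
    multispectral scenes with class-specific phenology, cloud
    contamination and spatially autocorrelated label maps, so the whole
    pipeline runs end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    nnet,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
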
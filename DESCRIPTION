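Package: spcdrift
Title: Statistical Process Control for Out-of-Distribution Detection and
    Data-Drift Monitoring in Imaging Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monitors streams of imaging data for out-of-distribution (OOD)
    inputs and temporal data drift by combining learned feature
    representations with geometric OOD metrics (cosine similarity,
    Mahalanobis distance) and statistical process control: three-sigma
    control charts flag individual OOD images, and CUSUM charts over daily
    mean metrics detect small sustained shifts in the input distribution.
    Includes a seeded drift-injection simulator, compact CPU-scale feature
    extractors (image-statistics baseline, autoencoder, supervised and
    contrastive encoders) for small grayscale images, and an evaluation
    protocol reporting sensitivity and specificity with bootstrap
    confidence intervals, false-alarm rates, and detection delays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
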
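Package: ddgate
Title: Data-Driven Respiratory Surrogate Signal Extraction for Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts respiratory surrogate signals from time series of
    low-resolution (optionally time-of-flight) PET sinograms, including
    acquisitions with strong early tracer kinetics. Implements conventional
    principal-component-analysis extraction with power-spectral-density
    scoring, a moving-window variant (PCA or spectral-analysis signed masks),
    re-use of a late-time-interval principal component for the whole
    acquisition, and a score-select-combine search over components. Ships the
    full pre-processing chain (Freeman-Tukey and Yeo-Johnson variance
    stabilisation, low-count masking, Gaussian smoothing with linear
    downsampling, temporal rebinning), trace post-processing (parallel
    compression, quartile outlier repair, windowed-sinc bandpass,
    Savitzky-Golay smoothing), a correlation-based evaluation harness, and a
    dynamic-PET phantom simulator with known respiratory and kinetic ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
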
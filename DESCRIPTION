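Package: rocketfp
Title: Neural Fingerprinting of Multivariate Time Series with Random
    Convolutional Kernel Transforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies individual subjects from short windows of
    multivariate neurophysiological time series ("neural fingerprinting").
    Implements the random convolutional kernel transform (ROCKET) and its
    fixed-kernel variant (MiniRocket) with proportion-of-positive-values
    pooling, a cross-validated ridge classifier, subject-level
    leave-one-out evaluation, parameter sweeps over kernel count, trial
    count and trial duration, and an empty-room cross-over control design.
    Includes a synthetic cohort generator that emulates region-level
    oscillatory source time courses with subject-specific spectral
    signatures and 1/f session noise, so the full pipeline can be
    exercised and validated without access to real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
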
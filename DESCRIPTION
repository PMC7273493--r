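Package: apneasound
Title: Apnea Detection from Tracheal Sounds with Adaptive Noise Cancellation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects apnea events from tracheal breath sounds recorded with a
    two-microphone setup. Implements normalized least-mean-squares (NLMS)
    adaptive noise cancellation of ambient noise using a reference microphone,
    band-passed log-variance breath segmentation, extraction of apnea events as
    breath absences exceeding 15 seconds, signal-to-noise-ratio evaluation of
    the denoising on synthetic mixtures, and event-level scoring (sensitivity,
    specificity, predictive values, accuracy, Cohen's kappa) against reference
    annotations. Includes a synthetic two-channel record generator with ground
    truth for end-to-end validation, WAV and event-table input/output, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    utils,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
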
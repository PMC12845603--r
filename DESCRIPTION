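Package: eareeg
Title: Stress and Mental Workload Assessment from Single-Channel In-Ear EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying stress and mental
    workload from single-channel in-ear EEG recordings sampled at 500 Hz.
    Provides a protocol-structured synthetic EEG generator (1/f background plus
    band-limited rhythms, subject random effects, artifacts, subjective stress
    ratings), zero-phase filtering and threshold-based segment quality control,
    a 35-feature bank (statistical, Hjorth, and band-power spectral features),
    cross-subject classifiers and within-subject regressors evaluated under
    subject-grouped cross-validation, exact and permutation-sampled
    Shapley-value feature attribution, and the protocol-level rank and
    repeated-measures statistics. All results are tibbles designed for
    pipe-based workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
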
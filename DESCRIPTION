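Package: remband
Title: Sleep-Bruxism Screening from Single-Channel REM-Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for classifying sleep bruxism from
    single-channel electroencephalography during rapid-eye-movement (REM)
    sleep. Reads polysomnography recordings (EDF) with hypnogram
    annotations, extracts 30-second REM epochs, decomposes them into
    delta, theta, alpha and beta bands with a Daubechies-5 discrete
    wavelet transform, estimates absolute and relative band power with
    Welch's method, and derives a 28-feature vector per epoch (band
    mean/SD/RMS, relative power, spectral ratios, absolute power and
    sample entropy). Features are screened with Shapiro-Wilk gated
    rank-sum tests and classified with a cross-validated CART decision
    tree. A seeded synthetic polysomnography generator with controlled
    band-power structure makes every stage testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
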
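Package: distillecg
Title: Knowledge Distillation for Single-Lead ECG Arrhythmia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trains a lightweight single-lead (lead II) ECG rhythm classifier
    by distilling a 12-lead teacher network built from residual
    squeeze-and-excitation convolutional blocks and LSTM layers. Provides a
    Chapman-style CSV reader with usability filtering and an 11-to-4 rhythm
    class merge, stratified splitting, resampling and per-lead z-score
    normalisation, a synthetic 12-lead ECG generator covering the four merged
    rhythm classes (AFIB, GSVT, SB, SR), temperature-softmax and KL
    distillation losses, plateau-scheduled Adam training, one-vs-rest
    confusion-matrix metrics with macro aggregation, and parameter/MAC model
    complexity profiling. The neural network layers (1-D convolution, batch
    normalisation, squeeze-and-excitation, LSTM) are implemented natively
    with BLAS-backed matrix arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    readr,
    signal,
    generics,
    withr,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
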
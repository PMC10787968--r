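Package: hdemg
Title: High-Density Surface EMG Movement-Intention Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A complete pipeline for decoding attempted hand, wrist, and
    forearm movements from high-density surface electromyography (HD-EMG)
    recorded by a multi-electrode forearm sleeve, aimed at rehabilitation
    neurotechnology after stroke. Provides a synthetic sleeve-recording
    simulator with known ground truth; causal Butterworth band-pass and
    notch preprocessing with 100 ms RMS binning, temporal context stacking
    and train-statistics normalization; dynamic cue-label alignment by
    minimizing within-segment squared residuals; PCA-based logistic
    regression and support vector machine classifiers and a fully-connected
    neural network trained with label smoothing and a one-cycle schedule;
    bin-accuracy, chance-level, confusion and cue success-rate metrics with
    movement-subset analyses; and an online decoder with probability
    thresholding and consecutive-sample debouncing, plus a replay harness
    with exact stream/batch equivalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    glmnet,
    e1071,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
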
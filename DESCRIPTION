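Package: myofatigue
Title: Muscle-Fatigue Monitoring from Surface EMG and Ultrasound Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for monitoring exercise-induced muscle fatigue
    from surface electromyography (SEMG) and B-mode ultrasound image
    sequences. Provides wavelet-threshold SEMG denoising with hard, soft and
    an improved threshold function; windowed time-domain (IEMG, RMS) and
    frequency-domain (mean power frequency) fatigue features; an LSTM
    fatigue-state classifier with SVM, back-propagation neural network and
    1-D CNN baselines; and ultrasound muscle-image analysis with normalized
    cross-correlation ROI tracking, muscle-thickness measurement and
    gray-level co-occurrence matrix texture features. A synthetic-data module
    generates ground-truthed SEMG signals and layered speckle phantoms so the
    whole pipeline can be exercised and validated without external
    recordings.
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
    nnet,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
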
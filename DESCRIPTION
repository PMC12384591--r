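Package: eegcam
Title: Interpretable EEG Emotion Classification with Grad-CAM Channel
    Attribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for interpretable EEG-based emotion recognition on
    DEAP-layout recordings (32 channels at 128 Hz, 3 s baseline plus 60 s
    stimulus, arousal/valence self-ratings on a 1-9 scale). Provides
    baseline-template subtraction and windowing, a regularized 2D
    convolutional network over 128 x 32 windows trained with Adam, Grad-CAM
    class activation maps on the final convolutional layer, per-electrode
    normalized contribution scores with threshold-based channel selection,
    subset-stability analysis via Pearson correlation, 10-fold
    cross-validation reporting, and a synthetic-trial generator with known
    planted discriminative channels for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
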
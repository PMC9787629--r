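Package: handhmm
Title: Continuous Hand-Action Prediction from Surface EMG with Windowed
    GMM-HMM Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the upcoming gesture in continuous multi-gesture hand
    actions from multichannel surface electromyography (sEMG). Each
    two-gesture action is modeled by a six-state left-to-right hidden Markov
    model with Gaussian emissions over windowed RMS features; decoding uses a
    sliding-window Viterbi algorithm whose per-state maxima are carried
    across windows (long-term memory), and a prediction event fires as soon
    as the decoded path enters the key state that begins the rear gesture.
    For actions with more than two gestures, model pruning restricts
    decoding to the group of models that share the predicted gesture as
    their front gesture and restarts probability accumulation at the
    detected key state. Includes a synthetic sEMG generator with frame-level
    ground truth, band-pass/notch preprocessing, RMS feature extraction,
    Baum-Welch training, and evaluation tooling (accuracy, confusion tables,
    trigger latency).
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
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
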
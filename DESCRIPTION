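Package: emgnetr
Title: Compact CNN Gesture Recognition from Surface EMG Scalograms
Version: 0.1.0
Authors@R: person("EMG", "Tools", email = "emgtools@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for hand-gesture recognition from 8-channel
    surface electromyography (sEMG) armband recordings sampled at 200 Hz.
    Segments recordings into 52-sample analysis windows, converts each
    channel to a Mexican-hat continuous-wavelet-transform scalogram (32
    scales, mean-pooled to 15 x 25), and classifies the resulting 8-channel
    tensors with EMGNet, a compact four-layer convolutional network with a
    convolutional classifier head and 34311 learnable parameters. Also
    provides the classical myoelectric feature sets (Hudgins time-domain,
    enhanced time-domain, NinaPro-style, sample-entropy pipeline) with LDA
    and SVM baselines, a synthetic sEMG generator for fully reproducible
    testing, loaders for delimited-text and NinaPro DB5 recordings, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
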
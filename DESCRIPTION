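Package: affectsda
Title: Emotion Recognition from Multimodal Physiological Signals with
    Stacked Denoising Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for binary valence/arousal/dominance
    recognition from multichannel EEG and peripheral physiological
    recordings. Provides a hand-engineered multi-domain feature bank
    (time-domain statistics, Hjorth parameters, non-stationary index,
    Higuchi fractal dimension, higher-order crossings, Welch spectra,
    power-law index, short-time band power, bispectral summaries,
    magnitude-squared coherence, hemispheric asymmetry, db4 wavelet and
    Hilbert-Huang features), hybrid filter-wrapper feature selection,
    channel-level data augmentation, stacked denoising autoencoders with
    greedy layer-wise pre-training and supervised fine-tuning, restricted
    Boltzmann machine and feed-forward/convolutional reference baselines,
    weighted decision fusion, and cross-subject / single-subject
    evaluation protocols. A synthetic generator emulating the geometry of
    preprocessed 32-subject affective EEG studies makes every stage
    testable without access to gated data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    rpart,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
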
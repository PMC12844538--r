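Package: museeg
Title: Multimodal Music-Emotion Regression from EEG and Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Continuous music-emotion regression on the valence-arousal
    circumplex (1-9 rating scale) from paired audio and 32-channel EEG
    recordings shaped like the DEAP preprocessed release. Extracts five
    spectral timbre descriptors from 1-second half-overlapping audio
    windows, band-resolved power-spectral-density peak features from
    band-limited EEG, and fuses a multilayer perceptron with two compact
    one-dimensional convolutional branches (raw waveform, per-channel PSD)
    whose outputs are summed into valence and arousal predictions. Includes
    a DEAP-shaped synthetic dataset generator with known generative links
    between signal properties and ratings, training with early stopping,
    MAE/MAPE/R-squared evaluation, an EEG-off ablation experiment, and
    per-electrode attribution of the trained model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
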
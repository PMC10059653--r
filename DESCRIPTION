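Package: affectstream
Title: Rule-Based Valence-Arousal Emotion Judgment from Streaming EDA and
    Pulse-Wave Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for streaming emotion-trend judgment from peripheral
    physiological signals. Generates labelled synthetic electrodermal
    activity (EDA) and photoplethysmography (PPG) sessions; preprocesses
    raw traces (hardware calibration, three-level wavelet denoising,
    zero-phase Butterworth low-pass filtering, min-max normalization);
    extracts pulse-wave fiducials (main wave, dicrotic anterior wave,
    dicrotic notch, dicrotic wave) and a catalogue of time-domain,
    frequency-domain and physiological features including BpNN50, range
    and first-difference mean; selects an optimal feature subset by PCA
    loading-weight thresholding followed by Pearson-correlation
    significance screening; classifies each 10-second window into a
    valence-arousal quadrant (HAPV, HANV, LANV, LAPV) with an adaptive
    normalized threshold and an auditable rule tree; trains a support
    vector machine baseline for head-to-head comparison; and maps
    sustained quadrant decisions to game-adaptation events with
    activation-count tabulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    pracma,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
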
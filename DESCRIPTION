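Package: semgfatigue
Title: Muscle Fatigue Recognition from Surface EMG via Wavelet Packet
    Denoising and Recurrent Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting exercise-induced muscle fatigue from surface
    electromyography (sEMG). Implements wavelet packet decomposition with
    Shannon-entropy best-tree selection, threshold shrinkage denoising with
    hard, soft and an improved smoothly-interpolating threshold function,
    heuristic SURE-style threshold estimation, windowed time- and
    frequency-domain feature extraction (RMS, integrated EMG, median and mean
    power frequency), and fatigue/non-fatigue classification with an LSTM
    network plus CNN and RBF-kernel SVM baselines. A seeded synthetic sEMG
    generator emulates the amplitude rise and spectral compression that
    accompany fatigue so that every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
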
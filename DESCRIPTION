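Package: semgwfm
Title: Lower-Limb sEMG Action Recognition with Channel-Weighted Features
    and a Tiered-Selection Genetic Algorithm SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for recognising lower-limb actions from multichannel
    surface electromyography (sEMG). Detects action onset by a sliding-frame
    energy method, extracts a fixed-length main feature segment, computes four
    per-channel features (mean absolute value, root mean square, Willison
    amplitude, and log wavelet-packet coefficient energy), fuses channels with
    energy-derived weights (the weighted feature method), and tunes the penalty
    and kernel parameters of a radial-basis-function support vector machine
    with a genetic algorithm that combines championship selection with a
    four-tier fitness-sorted scheme. Includes a synthetic 8-channel sEMG
    generator with known onsets and per-action muscle-energy profiles for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
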
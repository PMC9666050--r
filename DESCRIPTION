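Package: wpemg
Title: Hand-Movement Recognition from Surface EMG via Wavelet Packet Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for myoelectric hand-movement pattern recognition.
    Windowed multi-channel surface electromyography (sEMG) signals are
    decomposed with a three-level wavelet packet transform (five selectable
    orthonormal bases: sym3, fk8, dmey, db4, coif2), four time/frequency
    features (mean absolute value, root mean square, mean frequency, median
    frequency) are extracted from every terminal sub-band, the feature space
    is reduced by principal component analysis, and six hand movements are
    classified with k-nearest-neighbour, Gaussian-kernel support vector
    machine, or bagged decision trees. Includes group-aware cross-validated
    evaluation, experiment sweeps over wavelet basis, retained dimension,
    additive noise level and window size, a Kruskal-Wallis feature screen,
    a seeded synthetic sEMG generator, and readers for delimited-text and
    MATLAB v5 recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
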
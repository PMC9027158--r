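Package: cgpat
Title: Cyclic Group of Prime Order Patterns for Physiological Signal
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Textural feature extraction for one-dimensional physiological
    signals (such as multichannel EEG) using center-symmetric local binary
    patterns derived from cyclic groups of prime order, with multilevel
    maximum-absolute-pooling decomposition, iterative neighborhood component
    analysis feature selection, 1-nearest-neighbor classification under
    10-fold and leave-one-subject-out cross-validation, and iterative hard
    majority voting across channels.  Includes a seeded surrogate-EEG
    generator so the whole pipeline can be exercised without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
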
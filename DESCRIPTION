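Package: chewsense
Title: Classification of Ingestive and Facial Behaviors from Bilateral
    Glasses-Hinge Force Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for monitoring ingestive behavior with force sensors
    embedded in the hinges of a pair of glasses. Implements the
    lever-mechanics model that amplifies temporalis-muscle force at the
    hinge, a synthetic generator of bilateral hinge-force recordings for
    six behavior classes (natural head movement, left/right chewing,
    left/right wink, talking), windowed spectral preprocessing (3-second
    windows, Hann taper, periodogram PSD, zero-phase Butterworth low-pass
    filtering), an 84-dimensional temporal/spectral/cross-channel feature
    extractor, RBF-kernel support vector machine training with two-step
    exponential grid search under leave-one-subject-out cross-validation,
    and confusion-matrix evaluation with per-class precision, recall and
    F1 scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
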
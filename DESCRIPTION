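Package: erpcsp
Title: Band-Separated CSP Classification of Feedback-Locked ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying symptom groups from feedback-locked EEG.
    Subject-level event-related potentials are separated into delta and theta
    bands with windowed-sinc FIR filters, spatially filtered with shrinkage-
    regularized Common Spatial Patterns, and classified with support vector
    machines under repeated stratified cross-validation. Includes permutation
    tests for classifier significance, the Nadeau-Bengio corrected resampled
    t-test for model comparison, a synthetic-EEG generator with planted
    band-limited spatial effects for validation, and a plain-text epoch
    container with EDF/BDF import.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
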
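Package: s34detect
Title: Detection of Third and Fourth Heart Sounds in Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Adaptive detection of the third (S3) and fourth (S4) heart
    sounds in single-channel phonocardiogram recordings. Records are
    segmented into cardiac cycles with a Shannon-energy envelope, analysed
    with the Hilbert-Huang transform (empirical mode decomposition followed
    by Hilbert spectral analysis), and the maximal-amplitude instantaneous
    frequency-magnitude distribution of the diastolic intervals is
    clustered with k-means; the fewest-member group is projected back to
    time, classified as S3 or S4 by its position in diastole, and refined
    by an iterative periodicity criterion. Includes a synthetic
    phonocardiogram generator with ground-truth annotations and a
    cycle-level sensitivity/precision evaluator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
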
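Package: eegretrieve
Title: Zero-Shot EEG-to-Image Retrieval with Visuo-Semantic Feature Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding viewed images from multichannel EEG in a
    zero-shot retrieval framework. Implements fully automated statistical
    thresholding for EEG cleaning (bad-channel detection, spherical spline
    interpolation, epoch rejection, ICA-based ocular artefact removal,
    within-epoch channel repair), correlation-stability EEG feature
    selection, a fused visuo-semantic stimulus feature space (Gabor filter
    bank histograms, dense SIFT visual bag-of-words, HSV colour histograms,
    word-embedding semantics, range normalisation and PCA fusion),
    regularised linear EEG-to-feature mapping under leave-one-class-out
    cross-validation, and cumulative match characteristic (CMC) evaluation
    of gallery ranking. Ships a synthetic data generator emulating
    picture-naming EEG paradigms so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    signal,
    jsonlite,
    yaml,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
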
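Package: somniconn
Title: Sleep EEG Functional Connectivity and Stage Classification from
    Two-Channel Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-channel (Fpz-Cz, Pz-Oz) sleep EEG
    sampled at 100 Hz. Reads European Data Format (EDF) polysomnography
    recordings and EDF+ hypnograms, maps Rechtschaffen & Kales stage labels
    to the five AASM stages, and cuts labelled 30 second epochs. Each epoch
    is decomposed into six rhythm bands (delta, theta, alpha, beta, sleep
    spindle, sawtooth) with zero-phase Butterworth filters, and functional
    connectivity between the two derivations is estimated per band as
    histogram mutual information. Downstream tools compare connectivity
    across sleep stages, age groups and sexes with one-way ANOVA plus
    gated post-hoc pairwise tests, and run a balanced, repeated-split
    sleep-staging experiment with support-vector, k-nearest-neighbour and
    random-forest classifiers. A synthetic cohort generator with
    controllable per-band cross-channel coupling (and a closed-form
    Gaussian mutual-information oracle) makes the whole pipeline testable
    without any recording on disk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    randomForest,
    class,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
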
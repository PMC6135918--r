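Package: microstatr
Title: Resting-State EEG Microstate Segmentation, Dynamics, and Two-Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for resting-state EEG microstate analysis: band-pass
    filtering and common-average referencing of multichannel scalp EEG,
    extraction of topographies at global field power (GFP) peaks,
    polarity-invariant modified k-means clustering at the subject and group
    level with Krzanowski-Lai selection of the number of microstate classes,
    competitive back-fitting and segmentation into microstate sequences,
    per-subject dynamic features (mean duration, occurrence, coverage), and
    two-group inference via topographic permutation tests (TANOVA), pooled-SD
    effect sizes, linear mixed-effects contrasts, and Dirichlet regression for
    compositional coverage. Includes a semi-Markov synthetic EEG generator
    with planted microstate structure for validation, and a command-line
    interface tying the stages together.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    clue,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
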
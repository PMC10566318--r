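Package: hashdemux
Title: Demultiplexing, Benchmarking and Quality Control for Cell Hashing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns droplets in hashtag-oligo (HTO) multiplexed single-cell
    experiments to their samples of origin. Implements seven demultiplexing
    strategies spanning threshold rules on ambient-corrected log-fold changes,
    k-medoids clustering with negative-binomial thresholds, Gaussian and
    negative-binomial two-component mixture models fitted by
    expectation-maximization, kernel-density bimodal thresholding, and
    Bayesian model comparison of singlet/doublet/negative hypotheses. Includes
    a synthetic HTO experiment simulator with known ground truth, a
    ground-truth-aware benchmarking harness (per-label F-scores, category
    proportions, doublet misassignment breakdown), quality-control
    diagnostics for hashing quality, and readers/writers for MatrixMarket and
    CSV count matrices, assignment tables and truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    cluster,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    Rtsne,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
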
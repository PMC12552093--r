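Package: smrtmet
Title: De Novo DNA Methylation Detection from SMRT Sequencing Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage detection of prokaryotic DNA methylation (5mC, 6mA,
    4mC) from single-molecule real-time sequencing polymerase kinetics. A
    bidirectional GRU regression model trained on whole-genome-amplified
    (methylation-free) data learns the expected inter-pulse duration and
    pulse width of unmethylated sequence; a downstream BiGRU classifier
    integrates raw kinetics, the predicted unmethylated baseline and one-hot
    sequence through nine feature-integration strategies and is trained with
    focal loss and label smoothing. Includes a seeded synthetic kinetics
    simulator with known sequence-context ground truth, window construction
    with motif-aware positive/negative sampling, integrated-gradients
    attribution, and evaluation machinery (AUC, AUPR, DeLong's test for
    correlated ROC curves, Mann-Whitney strategy comparison, repeated
    re-partitioned training).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
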
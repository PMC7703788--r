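Package: contactlens
Title: Evaluation and Integration Toolkit for Protein Residue-Residue
    Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing protein residue-residue contact
    predictions and the multiple sequence alignments (MSAs) behind them.
    Computes the effective number of sequences (Neff) by 62 percent
    identity weighting, detects ab initio "hard domains" as long runs of
    below-median alignment coverage, integrates domain-level contact maps
    into full-length maps by probability replacement, manipulates stacks
    of contact maps predicted at multiple distance thresholds as a
    discrete inter-residue distance distribution, scores predictions
    against native structures with CASP-convention metrics (top L/k
    precision by separation range, coverage, ROC/AUC, mean false-positive
    distance, one-contact-per-residue filtering), and derives the
    receptive field of stacked convolutional predictors. A synthetic-data
    module generates MSAs with engineered redundancy and coverage dips,
    toy 3D chains, and noisy predicted maps so every operation is
    exercisable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
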
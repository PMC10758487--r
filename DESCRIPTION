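Package: dhupred
Title: Sequence-Based Prediction of Dihydrouridine Sites in RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts dihydrouridine (D) modification sites in transcriptomes
    from the 41-nt sequence context of candidate uridines. Provides window
    extraction from transcript FASTA and site tables, negative sampling,
    greedy redundancy reduction by sequence identity, eight sequence-derived
    feature encoders (one-hot, chemical property, electron-ion interaction
    pseudopotential, dinucleotide composition, accumulated nucleotide
    frequency, dinucleotide auto- and cross-covariance, and pseudo k-tuple
    nucleotide composition), F-score ranking with incremental feature
    selection, encoder-combination search, an RBF-kernel support vector
    machine with log-grid hyperparameter search plus logistic regression,
    random forest and naive Bayes baselines, rank-based evaluation (AUROC,
    AUPRC, sensitivity, specificity, accuracy), cross-species transfer
    evaluation, and a synthetic motif-planting data generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
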
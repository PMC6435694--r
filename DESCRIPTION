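Package: neuropeptidr
Title: Sequence-Based Classification, Design and Scanning of Insect Neuropeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting insect neuropeptide activity from peptide
    sequence. Encodes peptides as amino-acid composition, dipeptide
    composition, terminus (split) composition and terminus one-hot binary
    profiles; assembles labelled benchmarks with random-background or
    compositionally-matched hard negatives, stratified 80/20 train/validation
    splits and five-fold partitions; trains RBF/linear support vector
    machines, random forests, decision trees and naive Bayes classifiers with
    grid search; evaluates with sensitivity, specificity, accuracy, Matthews
    correlation coefficient and AUROC; characterises peptide sets by mean and
    positional residue composition and exclusive contiguous motifs; and
    supports in-silico single-mutant design and sliding-window protein
    scanning. Includes a seeded synthetic-peptide generator so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    randomForest,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
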
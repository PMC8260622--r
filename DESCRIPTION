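Package: utrdesign
Title: Design, Modeling and Sort-Seq Screen Analysis of 5' UTRs for
    Enhanced Protein Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for engineering 5' untranslated regions (5' UTRs)
    that enhance protein expression in mammalian cells. Quantifies
    per-transcript translation efficiency (TE) from paired ribosome
    profiling (Ribo-seq) and RNA-seq count tables; standardizes natural
    5' UTRs into fixed-length, AUG-free library members and assembles
    synthesis-ready oligos; extracts sequence features (k-mer
    frequencies, RNA folding energy, length, upstream ORFs); trains
    regression surrogates (random forest, elastic net, decision tree,
    SVM) mapping features to TE and mRNA level; evolves synthetic 5'
    UTRs with a genetic algorithm guided by the learned fitness; and
    analyzes FACS-bin sort-seq screens (read-to-library matching,
    median-of-ratios normalization, negative-binomial differential
    enrichment, hit calling). A synthetic-data generator with recorded
    ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    Rcpp,
    e1071,
    glmnet,
    randomForest,
    rlang,
    rpart,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
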
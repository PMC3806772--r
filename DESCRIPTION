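Package: indeltree
Title: Functional Effect Prediction for In-Frame Coding Indels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies in-frame (3n) coding insertions and deletions as
    gene-damaging or neutral with an interpretable decision-tree model.
    Provides small exact tandem-repeat detection and left-normalization of
    indel coordinates in repeat regions, protein-consequence calling from a
    reference genome and gene models, feature extraction from protein-domain,
    disorder and per-base conservation tracks, a published-rules engine with
    confidence scores, a C4.5-style decision-tree trainer with gain-ratio
    splits and pessimistic-error pruning, evaluation machinery (k-fold
    cross-validation, balanced resampling, greedy forward feature selection,
    MCC and ROC-AUC), and a synthetic fixture generator that emulates all
    required inputs so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
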
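Package: titrabench
Title: Titration-Design Benchmarking of Alignment-Free and Alignment-Based
    RNA-Seq Quantification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale benchmarking framework for total RNA-seq
    quantification built around the MAQC-style titration design. Simulates a
    mixed transcriptome of long genes, ERCC-like spike-ins in designed ratio
    groups, and short modification-bearing tRNA-like transcripts; generates
    titrated samples (C and D as 3:1 and 1:3 mass mixtures of references A
    and B), replicate counts, and reads carrying misincorporation errors at
    modification sites. Provides two quantifiers over the same reads, a
    k-mer equivalence-class EM estimator and a mismatch-tolerant alignment
    pipeline with multi-mapping selection heuristics and anticodon
    aggregation, plus evaluation machinery: the expected C/D fold-change
    model, R-squared and RMSE by stratum, spike-in ROC/AUC, and the
    error-free k-mer combinatorics that explain alignment-free dropout on
    short RNAs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'design.R'
    'utils.R'
    'abundance.R'
    'reads.R'
    'align.R'
    'eval.R'
    'kmer.R'
    'transcriptome.R'
    'benchmark.R'
    'dropout.R'
    'titrabench-package.R'
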
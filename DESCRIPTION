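Package: lrescout
Title: Discovery of Labelled Regulatory Elements from TF Cistromes and
    Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates transcription-factor ChIP-seq cistromes with
    ATAC-seq open-chromatin peaks to classify regulatory regions into
    labelled regulatory elements (LREs, TF-bound but low accessible) and
    highly accessible classes; predicts chromatin openness from TF
    occupancy with a systematic feature-subset machine-learning sweep
    (random forest classification and support vector regression); clusters
    time-course elongating-polymerase signal into kinetic enhancer classes;
    and ships a ground-truthed synthetic-data generator so every stage is
    testable without sequencing data. Genomic interval set algebra (merge,
    consensus, subtract, blacklist filtering, promoter annotation) is built
    on GenomicRanges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust
Config/testthat/edition: 3
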
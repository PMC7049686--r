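Package: deepCobind
Title: Differential Deep Learning of Tissue-Specific Co-Factor Binding
    Features
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers tissue-specific co-factor binding features from
    differential transcription-factor ChIP-seq. Provides shallow
    (DeepBind-like) and deep (Basenji-like, bottlenecked, dilated,
    hyper-residual) convolutional models for classification of
    differential binding and regression of per-replicate log-RPKM;
    transfer, serial and parallel multitask regularization of the
    high-dimensional classification task with the larger regression
    task; nucleotide-level attribution by in silico mutagenesis,
    integrated gradients and gradient-times-input with completeness
    diagnostics; sliding-window feature ranking; a motif-centre Poisson
    test against validation ChIP read profiles; a cross-model feature
    stability estimator; and a synthetic-data generator with known
    ground-truth co-factor sites so the whole pipeline is testable
    without external data. A compact neural-network engine (exact
    analytic gradients for all layers) is included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
LinkingTo: Rcpp
biocViews: Epigenetics, Transcription, ChIPSeq, DeepLearning,
    FeatureExtraction, Classification, Regression
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
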
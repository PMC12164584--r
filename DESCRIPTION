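Package: chromattn
Title: Sequence-Based Prediction of Chromatin Features and Regulatory Variant Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-label epigenomic datasets from narrowPeak calls by
    binning the genome into 200-bp windows, trains a convolution-plus-attention
    neural network that predicts chromatin accessibility, histone modification
    and transcription-factor binding labels from 2000-bp DNA windows, and
    prioritizes noncoding single-nucleotide variants by in-silico mutagenesis:
    per-label SNP activity difference (SAD) scores and empirical E-values
    computed against a resampled pool of non-regulatory control variants.
    Includes a self-contained synthetic-data generator (random genome with
    planted motifs, derived peak tracks and effect-labelled variants) so the
    whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
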
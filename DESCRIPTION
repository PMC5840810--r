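Package: damo
Title: Discriminative Additive Motif Optimization for ChIP-Seq Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminative optimization of transcription-factor binding
    motifs from positive and negative sequence sets, as produced by ChIP-seq
    experiments. Implements perceptron-based training of position weight
    matrices (single-nucleotide or adjacent-dinucleotide) that maximizes the
    area under the ROC curve, seeded from JASPAR-style position frequency
    matrices; window extraction around peak summits with paired downstream
    negatives; best-site scanning on both strands; ten-fold cross-validated
    AUROC/AUPRC evaluation with tie-exact metric implementations; a
    feature-vector framework (4-bit sequence encoding, matrix-score and
    DNA-shape feature blocks) for pluggable binary classifiers; and seeded
    synthetic-data generators (planted-motif sequence sets, toy genomes with
    peaks, fabricated shape tracks) so the whole pipeline runs without any
    external download.
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
    ggplot2,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    jsonlite,
    withr
Config/testthat/edition: 3
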
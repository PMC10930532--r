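Package: yaptazsig
Title: Consensus YAP/TAZ-TEAD Transcriptional Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a consensus YAP/TAZ transcriptional signature from oriented
    differential-expression contrasts across melanoma cell lines, scores the
    signature in cell-line and tumor cohorts with from-scratch GSEA and
    single-sample (GSVA-style) enrichment statistics, binarizes CRISPR Chronos
    dependency scores to evaluate how well enrichment predicts YAP/TAZ/TEAD
    dependence via ROC analysis, validates the signature against marker-anchored
    Spearman correlation structure in tumor cohorts, and annotates ChIP-seq peaks
    to genes with a strand-aware TSS-window priority cascade. A synthetic-data
    module generates every input with the statistical structure the analysis
    assumes, so the full pipeline runs end to end with no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
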
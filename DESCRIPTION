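Package: netdlnc
Title: Long Non-Coding RNA Discovery and Temporal Classification in
    Neuroendocrine Transdifferentiation of Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering long non-coding RNAs
    (lncRNAs) associated with neuroendocrine transdifferentiation (NEtD)
    of prostate adenocarcinoma. Covers windowed-adaptive FASTQ quality
    trimming and library filters, construction of an lncRNA catalogue from
    Ensembl-style annotation (antisense, lincRNA and pseudogene subclasses
    with immunoglobulin/T-cell-receptor removal), expression flooring and
    cross-cohort identifier unification, gated two-group differential
    expression, four-class temporal classification of a patient-derived
    xenograft time series with model-to-clinic integration, cross-cohort
    variance-based expression signatures, transcription-factor binding-site
    over-representation via a continuity-corrected z-score, class-specific
    transcript ranking, microarray probe liftover by exon containment, and
    outcome stratification (ROC/AUC for rapid metastasis, Kaplan-Meier
    median dichotomization, qPCR delta-delta-Ct arithmetic). A synthetic
    data module generates every input with planted, recoverable structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
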
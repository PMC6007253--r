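# netdlnc

Long non-coding RNA (lncRNA) discovery and temporal classification in
neuroendocrine transdifferentiation (NEtD) of prostate cancer.

Neuroendocrine prostate cancer (NEPC) is an aggressive,
androgen-receptor-negative subtype that can arise from adenocarcinoma
(AD) under androgen deprivation therapy. `netdlnc` is an R package for
researchers studying this transition at the transcriptome level. It
implements, as composable and tested functions, the full multi-stage
discovery pipeline around a patient-derived xenograft (PDX) time series
and clinical cohorts:

* **Read QC** — windowed-adaptive quality trimming (Phred threshold 20,
  window 10% of read length, two-thirds length rule), synchronized pair
  handling, and removal of exact sequences above 2% of the library.
* **Catalogue** — Ensembl GTF parsing; the lncRNA catalogue keeps
  antisense, lincRNA and pseudogene subclasses and removes Ig/TCR
  pseudogenes; expression below 0.1 is floored; cross-cohort identifiers
  unify on (transcript id, length); clone-style names are dropped.
* **Differential expression** — equal-variance Student t-test with the
  joint gate (fold change ≥ 2 in either direction and *P* < 0.05),
  BH/Bonferroni adjustment reported alongside.
* **Temporal classes** — each transcript's trajectory across
  AD → postTX → NEPC is labelled Class I (Deactivated, continuous
  decline), II (Activated, single-step rise), III (Persistent,
  continuous rise) or IV (Transient, postTX peak), then intersected
  with the clinical gates to form the NEtD lncRNA sets.
* **Signature** — top fifth percentile of transcripts by SD of log2
  expression per cohort, intersected across cohorts and re-clustered
  (1 − Pearson, average linkage); concordant >10-fold members flagged.
* **TFBS enrichment** — IUPAC consensus scanning and the
  continuity-corrected over-representation z-score
  `z = (x − E − 0.5)/S`, significant at `|z| > 2`; unique-per-class and
  common-to-all-classes motif logic; presence distributions.
* **Clinical outcomes** — class-specific fold-change ranking (5 groups
  × 20 = 100 candidates), microarray probe liftover by exact exon
  containment, Mann-Whitney ROC AUC for rapid metastasis (< 36 months
  post-ADT vs ≥ 10-year metastasis-free controls), Kaplan-Meier median
  dichotomization with the log-rank test, and qPCR ΔΔCt arithmetic
  (fold change `2^(−ΔΔCt)`).
* **Synthetic data** — deterministic generators for every input (PDX
  series, clinical cohorts, outcome cohort with treatment-linked
  hazards, promoters with planted motifs, FASTQ, probe maps), each with
  a truth table so recovery can be measured exactly.

See the vignette (`vignettes/netd-lncrna-pipeline.Rmd`) for the models,
parameter meanings and design rationale.

## Worked example

```r
library(netdlnc)

cfg <- simulation_config(seed = 1)

# PDX time series -> temporal classes
pdx <- generate_pdx_timeseries(cfg)
asn <- assign_class(summarize_timepoints(pdx$matrix, pdx$metadata))
table(asn$class_label)
#>  I_Deactivated   II_Activated III_Persistent   IV_Transient   Unclassified
#>             50             50             50             50            800

# clinical cohorts -> gated differential expression
cl <- generate_clinical_cohorts(cfg)
res <- compare_groups(cl$A$matrix, cl$A$metadata, "NEPC_vs_AD")
sum(res$passes_gate)
#> [1] 180

# cross-cohort signature and its cluster purity
labels <- function(md)
  setNames(ifelse(md$phenotype_group == "NEPC", "NEPC", "AD"),
           md$sample_id)
sig <- derive_signature(cl$A$matrix, labels(cl$A$metadata),
                        cl$B$matrix, labels(cl$B$metadata))
length(sig$signature); sig$purity
#> [1] 30
#> A B
#> 1 1

# outcome stratification: effect only in the ADT-treated arm
oc <- generate_outcome_cohort(cfg)
km_median_split(oc$matrix["OTX_PRED01", ], oc$metadata,
                "treated")$logrank_p
#> [1] 2.47e-11
km_median_split(oc$matrix["OTX_PRED01", ], oc$metadata,
                "untreated")$logrank_p
#> [1] 0.312
```

The 200 planted temporal transcripts are recovered into their four
classes (the 800 remaining rows, including the planted signature, are
flat across the PDX stages and stay Unclassified). In cohort A, 180
transcripts pass the 2-fold / *P* < 0.05 gate — the 150 planted
NEPC-deregulated transcripts plus the planted 16-fold signature. The
30-member signature separates NEPC from AD with purity 1 in both
cohorts, and the planted predictive transcript stratifies time to
metastasis only in the treated arm.

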
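#' @name clinical_outcomes
#' @title Ranking, probe liftover and outcome stratification
#'
#' @description
#' Downstream clinical evaluation of the NEtD/NEPC lncRNA candidates:
#' class-specific ranking by clinical fold change, liftover of microarray
#' probe set regions onto sequenced exons (a probe maps only when fully
#' contained in an exon), ROC/AUC for predicting rapid metastasis within
#' 36 months of androgen deprivation therapy, Kaplan-Meier stratification
#' by median expression with a log-rank test, and relative qPCR
#' quantification via delta-delta-Ct.
NULL

fc_magnitude <- function(fc) pmax(fc, 1 / fc)

# named vector of per-transcript fold change for one comparison label
fc_lookup <- function(results, comparison) {
  rows <- results[results$comparison == comparison, , drop = FALSE]
  setNames(rows$fold_change, rows$transcript_key)
}

#' Rank class transcripts by clinical fold change
#'
#' Ranking keys per temporal class:
#' \itemize{
#'   \item Class I (Deactivated): the minimum fold change across
#'     NEPC-vs-AD, CRPC-vs-AD and NHT-vs-naive (all expected < 1);
#'     ordered ascending so the strongest decline ranks first.
#'   \item Class II / III (Activated / Persistent): the NEPC-vs-AD fold
#'     change per cohort, taking the maximum across cohorts; ordered by
#'     descending magnitude.
#'   \item Class IV (Transient): the magnitudes of the AD-vs-NHT and
#'     NHT-vs-NEPC fold changes, taking the maximum of the two; ordered
#'     descending.
#' }
#' The NEPC signature contributes one further group holding its
#' highest- and lowest-expressed transcripts in NEPC vs AD (cross-cohort
#' concordant; half from each end), giving five groups of `top_n`
#' selections.
#'
#' @param netd_sets Named list of transcript keys per class (from
#'   [integrate_clinical()]).
#' @param results_a,results_b Pooled [compare_groups()] results for the
#'   two cohorts (`results_b` may omit comparisons absent from that
#'   cohort).
#' @param signature_ranking Data frame from [rank_signature()].
#' @param top_n Selections per group (default 20).
#' @return A list with `per_class` (named list of ranking data frames),
#'   `selected` (data frame of the five groups' top picks, `group` and
#'   `transcript_key`) and `unique_keys` (duplicates collapsed).
#' @export
rank_class_transcripts <- function(netd_sets, results_a, results_b,
                                   signature_ranking, top_n = 20) {
  need <- function(results, comparison, cohort) {
    if (!comparison %in% results$comparison)
      stop(sprintf("missing comparison %s in cohort %s results",
                   comparison, cohort), call. = FALSE)
    fc_lookup(results, comparison)
  }
  rank_one <- function(cls, keys) {
    if (length(keys) == 0L)
      return(data.frame(transcript_key = character(), rank_key = numeric(),
                        stringsAsFactors = FALSE))
    if (cls == "I_Deactivated") {
      f1 <- need(results_a, "NEPC_vs_AD", "A")[keys]
      f2 <- need(results_a, "CRPC_vs_AD", "A")[keys]
      f3 <- need(results_a, "NHT_vs_NAIVE", "A")[keys]
      key <- pmin(f1, f2, f3)
      ord <- order(key, keys)                  # smallest = strongest down
    } else if (cls %in% c("II_Activated", "III_Persistent")) {
      fa <- need(results_a, "NEPC_vs_AD", "A")[keys]
      fb <- need(results_b, "NEPC_vs_AD", "B")[keys]
      key <- pmax(fa, fb)
      ord <- order(-fc_magnitude(key), keys)
    } else if (cls == "IV_Transient") {
      f1 <- fc_magnitude(need(results_a, "NHT_vs_NAIVE", "A")[keys])
      f2 <- fc_magnitude(need(results_a, "NEPC_vs_NHT", "A")[keys])
      key <- pmax(f1, f2)
      ord <- order(-key, keys)
    } else stop("unknown class: ", cls, call. = FALSE)
    data.frame(transcript_key = keys[ord], rank_key = unname(key[ord]),
               stringsAsFactors = FALSE)
  }
  per_class <- Map(rank_one, names(netd_sets), netd_sets)
  sig_up <- signature_ranking[signature_ranking$concordant &
                                signature_ranking$fc_a > 1, , drop = FALSE]
  sig_dn <- signature_ranking[signature_ranking$concordant &
                                signature_ranking$fc_a < 1, , drop = FALSE]
  groups <- c(
    lapply(per_class, function(d) head(d$transcript_key, top_n)),
    list(signature = c(head(sig_up$transcript_key, ceiling(top_n / 2)),
                       head(sig_dn$transcript_key, floor(top_n / 2)))))
  selected <- data.frame(
    group = rep(names(groups), lengths(groups)),
    transcript_key = unlist(groups, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(per_class = per_class, selected = selected,
       unique_keys = unique(selected$transcript_key))
}

#' Map microarray probes onto sequenced exons
#'
#' A probe set region maps to a transcript only when its interval is
#' entirely within one of the transcript's exons; straddling or
#' intergenic probes are excluded. Coordinates are 0-based half-open on
#' both sides.
#'
#' @param probes Data frame with `probe_id`, `chrom`, `start`, `end`.
#' @param exons Data frame with `transcript_id`, `chrom`, `start`, `end`.
#' @return A list with `mapping` (data frame `probe_id`,
#'   `transcript_id`), `measurable_transcripts` (>= 1 mapped probe) and
#'   `mapped_fraction` (probes mapped / probes supplied).
#' @export
map_probes <- function(probes, exons) {
  if (nrow(probes) == 0L)
    return(list(mapping = data.frame(probe_id = character(),
                                     transcript_id = character(),
                                     stringsAsFactors = FALSE),
                measurable_transcripts = character(),
                mapped_fraction = 0))
  if (any(probes$end <= probes$start) || any(exons$end <= exons$start))
    stop("malformed interval: end must be > start", call. = FALSE)
  # half-open [start, end) -> 1-based closed [start+1, end]
  pg <- GenomicRanges::GRanges(
    probes$chrom, IRanges::IRanges(probes$start + 1L, probes$end))
  eg <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start + 1L, exons$end))
  ov <- GenomicRanges::findOverlaps(pg, eg, type = "within",
                                    ignore.strand = TRUE)
  mapping <- unique(data.frame(
    probe_id = probes$probe_id[S4Vectors::queryHits(ov)],
    transcript_id = exons$transcript_id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE))
  rownames(mapping) <- NULL
  list(mapping = mapping,
       measurable_transcripts = sort(unique(mapping$transcript_id)),
       mapped_fraction = length(unique(mapping$probe_id)) / nrow(probes))
}

#' Mann-Whitney ROC AUC with midrank ties
#'
#' The probability that a random positive scores above a random negative,
#' computed from ranks with the midrank tie correction; equal to the
#' trapezoidal area under the ROC curve.
#'
#' @param scores Numeric predictor (higher = more positive).
#' @param labels Logical or 0/1 outcome; both values must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both label values must be present", call. = FALSE)
  r <- rank(scores)                       # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Label samples for the rapid-metastasis contrast
#'
#' Positives are ADT-treated samples with a metastasis event before
#' `rapid_months`; negatives are ADT-treated samples with no event and at
#' least `min_followup_months` of follow-up. All other samples (untreated,
#' slow events, short follow-up) are excluded (`NA`).
#'
#' @param metadata Data frame with `adt_treated`, `metastasis_event`,
#'   `time_to_metastasis_months` and `followup_months` columns.
#' @param rapid_months Rapid-metastasis window (default 36).
#' @param min_followup_months Minimum control follow-up (default 120,
#'   i.e. ten years).
#' @return Logical vector (TRUE/FALSE/NA) aligned with `metadata` rows.
#' @export
define_rapid_met_groups <- function(metadata, rapid_months = 36,
                                    min_followup_months = 120) {
  lab <- rep(NA, nrow(metadata))
  pos <- metadata$adt_treated & !is.na(metadata$metastasis_event) &
    metadata$metastasis_event &
    metadata$time_to_metastasis_months < rapid_months
  neg <- metadata$adt_treated & !is.na(metadata$metastasis_event) &
    !metadata$metastasis_event &
    metadata$followup_months >= min_followup_months
  lab[pos] <- TRUE
  lab[neg] <- FALSE
  lab
}

#' Kaplan-Meier stratification by median expression
#'
#' Splits one treatment arm at the median of a transcript's expression
#' (ties to the low group), fits the product-limit estimator per group
#' and tests separation with the two-group log-rank test (1 df).
#'
#' @param expression Named numeric vector of expression per sample.
#' @param metadata Data frame with `sample_id`, `adt_treated`,
#'   `time_to_metastasis_months`, `metastasis_event`, `followup_months`.
#' @param arm `"treated"` or `"untreated"`.
#' @return A list with `fit` (a `survfit` object over groups low/high),
#'   `logrank_p`, `chisq` and `groups` (named factor).
#' @export
km_median_split <- function(expression, metadata,
                            arm = c("treated", "untreated")) {
  arm <- match.arg(arm)
  md <- metadata[if (arm == "treated") metadata$adt_treated
                 else !metadata$adt_treated, , drop = FALSE]
  x <- expression[md$sample_id]
  event <- !is.na(md$metastasis_event) & md$metastasis_event
  time <- ifelse(event, md$time_to_metastasis_months, md$followup_months)
  if (all(time <= 0)) stop("no positive follow-up times", call. = FALSE)
  group <- factor(ifelse(x > median(x), "high", "low"),
                  levels = c("low", "high"))
  if (min(table(group)) < 2L)
    stop("need >= 2 samples per median-split group", call. = FALSE)
  surv <- survival::Surv(time, event)
  fit <- survival::survfit(surv ~ group)
  sd_ <- survival::survdiff(surv ~ group)
  p <- 1 - pchisq(sd_$chisq, df = 1)
  list(fit = fit, logrank_p = p, chisq = unname(sd_$chisq),
       groups = setNames(group, md$sample_id))
}

#' Relative quantification by delta-delta-Ct
#'
#' Averages Ct across technical triplicates, references each target to a
#' housekeeper within sample (delta Ct), then to a reference sample
#' (delta-delta Ct), and reports the fold change `2^(-ddCt)`.
#'
#' @param ct Data frame with columns `target`, `sample` and `ct`
#'   (triplicate rows per target/sample pair).
#' @param housekeeper_id Target name of the housekeeping gene.
#' @param reference_sample Sample name used as the comparator.
#' @return Data frame: `target`, `sample`, `ct_mean`, `ct_sd`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change` (housekeeper and
#'   reference-sample rows included, with fold 1 for the reference).
#' @export
ddct_fold_change <- function(ct, housekeeper_id, reference_sample) {
  if (!housekeeper_id %in% ct$target)
    stop("missing housekeeper: ", housekeeper_id, call. = FALSE)
  agg <- stats::aggregate(ct$ct, by = list(target = ct$target,
                                           sample = ct$sample),
                          FUN = function(v) c(mean = mean(v), sd = sd(v)))
  res <- data.frame(target = agg$target, sample = agg$sample,
                    ct_mean = agg$x[, "mean"], ct_sd = agg$x[, "sd"],
                    stringsAsFactors = FALSE)
  hk <- res[res$target == housekeeper_id, c("sample", "ct_mean")]
  res$delta_ct <- res$ct_mean -
    hk$ct_mean[match(res$sample, hk$sample)]
  ref <- res[res$sample == reference_sample, c("target", "delta_ct")]
  if (nrow(ref) == 0L)
    stop("missing reference sample: ", reference_sample, call. = FALSE)
  res$delta_delta_ct <- res$delta_ct -
    ref$delta_ct[match(res$target, ref$target)]
  res$fold_change <- 2^(-res$delta_delta_ct)
  res[res$target != housekeeper_id, , drop = FALSE]
}
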
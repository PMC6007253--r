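#' @name diffexp
#' @title Gated group-wise differential expression
#'
#' @description
#' Two-group comparisons between phenotype groups (e.g. NEPC vs AD) with
#' the pipeline's joint gate: a transcript passes when its linear fold
#' change is at least 2 in either direction and the two-sided Student
#' t-test p-value is below 0.05. Adjusted p-values (Benjamini-Hochberg or
#' Bonferroni) are always reported but the default gate uses raw p-values;
#' the multiple-testing burden is instead absorbed by the downstream
#' filter-down integration steps.
NULL

# comparison label -> c(reference group, test group); fold change and
# direction are test relative to reference
COMPARISON_GROUPS <- list(
  NEPC_vs_AD   = c("AD", "NEPC"),
  NEPC_vs_NHT  = c("NHT", "NEPC"),
  CRPC_vs_AD   = c("AD", "CRPC"),
  NHT_vs_NAIVE = c("AD_NAIVE", "NHT"),
  PDX_pre_vs_post = c("PDX_AD", "PDX_NEPC")
)

#' Two-sided equal-variance Student t-test
#'
#' @param a,b Numeric vectors, each with at least two values.
#' @return A list with `t` and `p` (classical pooled-variance t with
#'   `length(a) + length(b) - 2` degrees of freedom). Zero pooled variance
#'   with equal means yields `t = 0, p = 1`; with unequal means an error.
#' @export
t_test_two_sided <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Linear fold change with pseudocount
#'
#' @param mean_a Reference group mean (>= 0).
#' @param mean_b Test group mean (>= 0).
#' @param pseudocount Added to both means before the ratio; default 0.1,
#'   the expression flooring constant.
#' @return A list with `fold_change` (`(mean_b + pc) / (mean_a + pc)`),
#'   `direction` (`"up"` if > 1 else `"down"`) and `undefined` (TRUE when
#'   both means and the pseudocount are zero; the ratio is then reported
#'   as 1).
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = 0.1) {
  if (mean_a < 0 || mean_b < 0) stop("means must be >= 0", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (mean_a + pseudocount == 0 && mean_b + pseudocount == 0)
    return(list(fold_change = 1, direction = "up", undefined = TRUE))
  fc <- (mean_b + pseudocount) / (mean_a + pseudocount)
  list(fold_change = fc, direction = if (fc > 1) "up" else "down",
       undefined = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param method `"benjamini_hochberg"` or `"bonferroni"`.
#' @return Adjusted p-values, clipped at 1.
#' @export
adjust_p <- function(p_values, method = c("benjamini_hochberg",
                                          "bonferroni")) {
  method <- match.arg(method)
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  p.adjust(p_values,
           method = switch(method, benjamini_hochberg = "BH",
                           bonferroni = "bonferroni"))
}

# core per-transcript engine for one reference/test group pair
compare_two_groups <- function(matrix, metadata, ref_group, test_group,
                               label, fc_gate = 2, p_gate = 0.05,
                               pseudocount = 0.1) {
  ids_a <- metadata$sample_id[metadata$phenotype_group == ref_group]
  ids_b <- metadata$sample_id[metadata$phenotype_group == test_group]
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stop(sprintf("comparison %s needs >= 2 samples per group (%s: %d, %s: %d)",
                 label, ref_group, length(ids_a), test_group,
                 length(ids_b)), call. = FALSE)
  a <- matrix[, ids_a, drop = FALSE]
  b <- matrix[, ids_b, drop = FALSE]
  la <- log2p(a, pseudocount); lb <- log2p(b, pseudocount)
  n <- nrow(matrix)
  res <- data.frame(
    transcript_key = rownames(matrix), comparison = label,
    mean_a = rowMeans(a), mean_b = rowMeans(b),
    fold_change = NA_real_, direction = NA_character_,
    t_statistic = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fc <- fold_change(res$mean_a[i], res$mean_b[i], pseudocount)
    res$fold_change[i] <- fc$fold_change
    res$direction[i] <- fc$direction
    xa <- la[i, ]; xb <- lb[i, ]
    if (stats::var(xa) + stats::var(xb) == 0) {
      # degenerate noiseless case: identical groups are null, separated
      # groups are unambiguously different
      if (mean(xa) == mean(xb)) {
        res$t_statistic[i] <- 0; res$p_value[i] <- 1
      } else {
        res$t_statistic[i] <- sign(mean(xa) - mean(xb)) * Inf
        res$p_value[i] <- 0
      }
    } else {
      tt <- t_test_two_sided(xa, xb)
      res$t_statistic[i] <- tt$t
      res$p_value[i] <- tt$p
    }
  }
  res$p_adjusted <- adjust_p(res$p_value, "benjamini_hochberg")
  res$passes_gate <- (res$fold_change >= fc_gate |
                        res$fold_change <= 1 / fc_gate) &
    res$p_value < p_gate
  rownames(res) <- NULL
  res
}

#' Group-wise differential expression with the pipeline gate
#'
#' Runs one of the defined phenotype comparisons over every transcript.
#' The t-test operates on `log2(x + pseudocount)` (the noise model is
#' log-normal) while fold changes stay on linear expression. Comparison
#' `COMBINED_E` is the intersection of the `NHT_vs_NAIVE` and
#' `NEPC_vs_NHT` gates: a transcript passes only if it passes both.
#'
#' @param matrix Expression matrix (transcripts x samples).
#' @param metadata Data frame with `sample_id` and `phenotype_group`
#'   columns covering the matrix columns.
#' @param comparison One of `NEPC_vs_AD`, `NEPC_vs_NHT`, `CRPC_vs_AD`,
#'   `NHT_vs_NAIVE`, `COMBINED_E`, `PDX_pre_vs_post`.
#' @param fc_gate Linear fold-change gate (default 2; both directions).
#' @param p_gate Raw p-value gate (default 0.05).
#' @param pseudocount Pseudocount for ratios and the log transform.
#' @return Data frame, one row per transcript: `transcript_key`,
#'   `comparison`, `mean_a`, `mean_b`, `fold_change`, `direction`,
#'   `t_statistic`, `p_value`, `p_adjusted`, `passes_gate`.
#' @export
compare_groups <- function(matrix, metadata, comparison, fc_gate = 2,
                           p_gate = 0.05, pseudocount = 0.1) {
  validate_expression(matrix)
  if (comparison == "COMBINED_E") {
    r1 <- compare_groups(matrix, metadata, "NHT_vs_NAIVE", fc_gate,
                         p_gate, pseudocount)
    r2 <- compare_groups(matrix, metadata, "NEPC_vs_NHT", fc_gate,
                         p_gate, pseudocount)
    res <- r2
    res$comparison <- "COMBINED_E"
    res$passes_gate <- r1$passes_gate & r2$passes_gate
    return(res)
  }
  if (!comparison %in% names(COMPARISON_GROUPS))
    stop("unknown comparison label: ", comparison, call. = FALSE)
  grp <- COMPARISON_GROUPS[[comparison]]
  ref <- grp[1]
  # cohorts label untreated adenocarcinoma either AD or AD_NAIVE
  if (!ref %in% metadata$phenotype_group && ref == "AD" &&
      "AD_NAIVE" %in% metadata$phenotype_group)
    ref <- "AD_NAIVE"
  compare_two_groups(matrix, metadata, ref, grp[2], comparison, fc_gate,
                     p_gate, pseudocount)
}

#' Partition gated transcripts into common and subtype-unique sets
#'
#' Given results from the two castration contrasts (progression to AR+
#' CRPC vs to AR- NEPC), split the gated transcripts into those
#' deregulated in both subtypes and those unique to one.
#'
#' @param results_ar_pos,results_ar_neg Data frames from
#'   [compare_groups()].
#' @return A list with `common`, `unique_ar_pos`, `unique_ar_neg`
#'   (character vectors of transcript keys) and `common_fraction`
#'   (common / all gated).
#' @export
pre_post_overlap <- function(results_ar_pos, results_ar_neg) {
  ga <- results_ar_pos$transcript_key[results_ar_pos$passes_gate]
  gb <- results_ar_neg$transcript_key[results_ar_neg$passes_gate]
  common <- intersect(ga, gb)
  all_gated <- union(ga, gb)
  list(common = common,
       unique_ar_pos = setdiff(ga, gb),
       unique_ar_neg = setdiff(gb, ga),
       common_fraction = if (length(all_gated) == 0L) NA_real_
         else length(common) / length(all_gated))
}
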
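#' @name netd_temporal
#' @title Temporal classification of the PDX transdifferentiation series
#'
#' @description
#' The patient-derived xenograft (PDX) model of neuroendocrine
#' transdifferentiation is sampled at three stages: androgen-dependent
#' adenocarcinoma (AD), post-castration regression (postTX; week 8 and
#' week 12), and relapsed neuroendocrine prostate cancer (NEPC). Each
#' transcript's stage means define a two-step trajectory that is assigned
#' one of four temporal classes: I Deactivated (continuous decline),
#' II Activated (a single-step rise), III Persistent (continuous rise) and
#' IV Transient (maximum at postTX); everything else is Unclassified.
#' Class assignments are then intersected with the clinical group-wise
#' comparisons to produce the NEtD lncRNA sets.
NULL

PDX_STAGES <- c("PDX_AD", "PDX_POSTTX_8W", "PDX_POSTTX_12W", "PDX_NEPC")

#' Stage means across the PDX time series
#'
#' @param matrix Expression matrix whose columns are PDX samples.
#' @param metadata Data frame with `sample_id` and `phenotype_group`
#'   columns; the groups `PDX_AD`, `PDX_POSTTX_8W`, `PDX_POSTTX_12W` and
#'   `PDX_NEPC` must all be present. postTX is the mean of the week-8 and
#'   week-12 samples.
#' @return Data frame with `transcript_key`, `expr_AD`, `expr_postTX`,
#'   `expr_NEPC` (arithmetic means on linear expression).
#' @export
summarize_timepoints <- function(matrix, metadata) {
  validate_expression(matrix)
  missing <- setdiff(PDX_STAGES, metadata$phenotype_group)
  if (length(missing) > 0L)
    stop("missing PDX stage(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ids <- function(groups)
    metadata$sample_id[metadata$phenotype_group %in% groups]
  stage_mean <- function(groups)
    rowMeans(matrix[, ids(groups), drop = FALSE])
  data.frame(
    transcript_key = rownames(matrix),
    expr_AD = stage_mean("PDX_AD"),
    expr_postTX = stage_mean(c("PDX_POSTTX_8W", "PDX_POSTTX_12W")),
    expr_NEPC = stage_mean("PDX_NEPC"),
    row.names = NULL, stringsAsFactors = FALSE)
}

# direction of one step at the given fold threshold
step_direction <- function(ratio, step_fold) {
  ifelse(ratio >= step_fold, "up",
         ifelse(ratio <= 1 / step_fold, "down", "flat"))
}

#' Assign temporal classes from stage profiles
#'
#' Each step ratio (postTX/AD and NEPC/postTX, with pseudocount) is called
#' up (>= `step_fold`), down (<= 1/`step_fold`) or flat. Labels:
#' \itemize{
#'   \item `I_Deactivated`: (down,down), (down,flat) or (flat,down), with
#'     the additional requirement that the overall AD-to-NEPC decline is
#'     at least `step_fold` (a "continuous decline" must show a net drop);
#'   \item `III_Persistent`: (up,up) -- checked before II;
#'   \item `IV_Transient`: (up,down), maximum at postTX;
#'   \item `II_Activated`: (up,flat) or (flat,up), a single-step rise;
#'   \item `Unclassified`: everything else, including (down,up) profiles
#'     (a postTX minimum defines no class) and flat profiles.
#' }
#'
#' @param profiles Data frame from [summarize_timepoints()].
#' @param step_fold Fold threshold per step, > 1 (default 2).
#' @param pseudocount Added to every stage mean before ratios.
#' @return Data frame with `transcript_key`, `class_label`, `step1_ratio`,
#'   `step2_ratio`, `overall_ratio`.
#' @export
assign_class <- function(profiles, step_fold = 2, pseudocount = 0.1) {
  if (step_fold <= 1) stop("'step_fold' must be > 1", call. = FALSE)
  if (any(profiles$expr_AD < 0 | profiles$expr_postTX < 0 |
            profiles$expr_NEPC < 0))
    stop("negative expression in profile", call. = FALSE)
  r1 <- (profiles$expr_postTX + pseudocount) /
    (profiles$expr_AD + pseudocount)
  r2 <- (profiles$expr_NEPC + pseudocount) /
    (profiles$expr_postTX + pseudocount)
  overall <- (profiles$expr_NEPC + pseudocount) /
    (profiles$expr_AD + pseudocount)
  d1 <- step_direction(r1, step_fold)
  d2 <- step_direction(r2, step_fold)
  label <- rep("Unclassified", nrow(profiles))
  decline <- (d1 == "down" & d2 == "down") |
    (d1 == "down" & d2 == "flat") | (d1 == "flat" & d2 == "down")
  label[decline & overall <= 1 / step_fold] <- "I_Deactivated"
  label[d1 == "up" & d2 == "up"] <- "III_Persistent"
  label[d1 == "up" & d2 == "down"] <- "IV_Transient"
  label[(d1 == "up" & d2 == "flat") | (d1 == "flat" & d2 == "up")] <-
    "II_Activated"
  data.frame(transcript_key = profiles$transcript_key,
             class_label = label, step1_ratio = r1, step2_ratio = r2,
             overall_ratio = overall, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Default class-to-comparison integration mapping
#'
#' For each temporal class, the clinical comparisons and directions whose
#' gated transcripts the class is intersected with. A class transcript is
#' retained if it is gated (in the required direction) in any of the
#' listed comparisons.
#'
#' @return Named list: per class, a data frame of `comparison` and
#'   `direction` (`"up"`, `"down"` or `"any"`).
#' @export
default_integration_mapping <- function() {
  list(
    I_Deactivated = data.frame(
      comparison = c("NEPC_vs_AD", "CRPC_vs_AD", "NHT_vs_NAIVE"),
      direction = "down", stringsAsFactors = FALSE),
    II_Activated = data.frame(
      comparison = c("NEPC_vs_AD", "NEPC_vs_NHT"),
      direction = "up", stringsAsFactors = FALSE),
    III_Persistent = data.frame(
      comparison = "NEPC_vs_AD", direction = "up",
      stringsAsFactors = FALSE),
    IV_Transient = data.frame(
      comparison = "COMBINED_E", direction = "any",
      stringsAsFactors = FALSE)
  )
}

#' Integrate temporal classes with clinical comparisons
#'
#' Intersects each temporal class with the clinically gated transcript
#' sets according to a mapping (default [default_integration_mapping()]).
#'
#' @param assignments Data frame from [assign_class()].
#' @param clinical_results List of data frames from [compare_groups()]
#'   (any cohorts; rows are pooled per comparison label).
#' @param mapping Class-to-comparison mapping; see
#'   [default_integration_mapping()].
#' @return A list with `sets` (named list of transcript keys per class)
#'   and `summary` (data frame of per-class counts before and after
#'   integration).
#' @export
integrate_clinical <- function(assignments, clinical_results,
                               mapping = default_integration_mapping()) {
  known <- c("I_Deactivated", "II_Activated", "III_Persistent",
             "IV_Transient")
  if (!all(names(mapping) %in% known))
    stop("unknown class in mapping: ",
         paste(setdiff(names(mapping), known), collapse = ", "),
         call. = FALSE)
  pooled <- do.call(rbind, clinical_results)
  gated_keys <- function(comparison, direction) {
    rows <- pooled[pooled$comparison == comparison & pooled$passes_gate, ,
                   drop = FALSE]
    if (direction != "any")
      rows <- rows[rows$direction == direction, , drop = FALSE]
    unique(rows$transcript_key)
  }
  sets <- list()
  counts <- data.frame(class_label = names(mapping), n_model = NA_integer_,
                       n_integrated = NA_integer_,
                       stringsAsFactors = FALSE)
  for (i in seq_along(mapping)) {
    cls <- names(mapping)[i]
    in_class <- assignments$transcript_key[assignments$class_label == cls]
    rules <- mapping[[i]]
    keys <- character()
    if (!is.null(pooled) && nrow(rules) > 0L)
      keys <- unique(unlist(Map(gated_keys, rules$comparison,
                                rules$direction)))
    sets[[cls]] <- intersect(in_class, keys)
    counts$n_model[i] <- length(in_class)
    counts$n_integrated[i] <- length(sets[[cls]])
  }
  list(sets = sets, summary = counts)
}
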
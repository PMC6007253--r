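#' @name tfbs_enrichment
#' @title Transcription factor binding site enrichment
#'
#' @description
#' Motif over-representation in promoter sequences of the temporal-class
#' lncRNA sets, scored with the continuity-corrected z-score
#' `z = (x - E - 0.5) / S`, where `x` is the observed match count, `E`
#' the expected count under the background and `S` its standard
#' deviation. Motifs with `|z| > 2` (two-sided normal p of about 0.05)
#' are called significant. Backgrounds may be supplied directly as
#' `(E, S)` pairs or derived from a per-position binomial model. Motifs
#' are IUPAC consensus strings scanned exactly (both strands by default,
#' overlapping matches counted); class-specific results are integrated
#' into unique-per-class and common-to-all-classes motif sets, and
#' presence/absence distributions across classes are tabulated.
NULL

IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

check_iupac <- function(motif) {
  letters <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(letters, IUPAC_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  toupper(motif)
}

#' Continuity-corrected over-representation z-score
#'
#' @param x Observed match count (>= 0).
#' @param E Expected count under the background.
#' @param S Standard deviation of the count under the background (> 0).
#' @return `(x - E - 0.5) / S`.
#' @export
enrichment_z <- function(x, E, S) {
  if (any(S <= 0)) stop("'S' must be > 0", call. = FALSE)
  (x - E - 0.5) / S
}

#' Two-sided normal tail probability for a z-score
#'
#' @param z Numeric z-score(s).
#' @return `2 * (1 - pnorm(abs(z)))`; `z = 2` gives about 0.0455,
#'   conventionally read as p of approximately 0.05.
#' @export
z_to_p <- function(z) {
  2 * (1 - pnorm(abs(z)))
}

#' Binomial background expectation for a motif count
#'
#' Models the number of matches among `n_positions` scanned positions as
#' binomial with per-position match probability `p`.
#'
#' @param n_positions Number of scanned positions.
#' @param p Per-position background match probability in \[0, 1\].
#' @return A list with `E = n * p`, `S = sqrt(n * p * (1 - p))` and
#'   `scorable` (FALSE when `S` is zero, i.e. `p` is 0 or 1).
#' @export
background_expectation <- function(n_positions, p) {
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]", call. = FALSE)
  E <- n_positions * p
  S <- sqrt(n_positions * p * (1 - p))
  list(E = E, S = S, scorable = S > 0)
}

#' Count IUPAC consensus matches in sequences
#'
#' Counts every position (overlapping matches included) where the
#' consensus pattern matches; with `both_strands` the reverse complement
#' of the motif is scanned as well, so palindromic motifs count twice.
#'
#' @param sequences Character vector of A/C/G/T sequences (or a
#'   `DNAStringSet`).
#' @param motif IUPAC consensus string, length >= 4.
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return Integer vector of hit counts, one per sequence.
#' @export
scan_consensus <- function(sequences, motif, both_strands = TRUE) {
  motif <- check_iupac(motif)
  if (nchar(motif) < 4L) stop("motif length must be >= 4", call. = FALSE)
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  pat <- Biostrings::DNAString(motif)
  counts <- Biostrings::vcountPattern(pat, sequences, fixed = FALSE)
  if (both_strands) {
    rc <- Biostrings::reverseComplement(pat)
    counts <- counts +
      Biostrings::vcountPattern(rc, sequences, fixed = FALSE)
  }
  as.integer(counts)
}

#' Class-wise motif enrichment from hit tables
#'
#' Scores each (class, motif) observed count against its background. The
#' background table supplies, per motif, either an explicit `(E, S)` pair
#' (used verbatim, e.g. from an external engine) or a per-position rate
#' `p` combined with the class's scanned position count.
#'
#' @param hits Data frame with columns `class_label`, `motif_id`, `x`
#'   (observed count) and, when a rate background is used, `n_positions`.
#' @param background Data frame with column `motif_id` plus either `E`
#'   and `S` columns or a `p` column.
#' @param z_cut Significance threshold on `|z|` (default 2).
#' @return Data frame: `class_label`, `motif_id`, `x`, `E`, `S`, `z`,
#'   `p_value`, `significant`. Motifs missing from the background, or
#'   with an unscorable background (`S = 0`), are skipped with a warning.
#' @export
class_enrichment <- function(hits, background, z_cut = 2) {
  has_es <- all(c("E", "S") %in% names(background))
  rows <- vector("list", nrow(hits))
  skipped <- character()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    b <- background[background$motif_id == h$motif_id, , drop = FALSE]
    if (nrow(b) == 0L) {
      skipped <- c(skipped, h$motif_id)
      next
    }
    if (has_es) {
      E <- b$E[1]; S <- b$S[1]
    } else {
      be <- background_expectation(h$n_positions, b$p[1])
      E <- be$E; S <- be$S
    }
    if (S <= 0) {
      skipped <- c(skipped, h$motif_id)
      next
    }
    z <- enrichment_z(h$x, E, S)
    rows[[i]] <- data.frame(
      class_label = h$class_label, motif_id = h$motif_id, x = h$x,
      E = E, S = S, z = z, p_value = z_to_p(z),
      significant = abs(z) > z_cut, stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L)
    warning("skipped motif(s) with missing or unscorable background: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(class_label = character(), motif_id = character(),
                      x = numeric(), E = numeric(), S = numeric(),
                      z = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Unique-per-class and common-to-all motifs
#'
#' @param results Data frame from [class_enrichment()] covering at least
#'   two classes.
#' @return A list with `unique_per_class` (named list: motifs significant
#'   in exactly that class) and `common` (motifs significant in every
#'   class).
#' @export
unique_and_common <- function(results) {
  classes <- unique(results$class_label)
  if (length(classes) < 2L) stop("need >= 2 classes", call. = FALSE)
  sig <- lapply(classes, function(cl)
    unique(results$motif_id[results$class_label == cl &
                              results$significant]))
  names(sig) <- classes
  n_sig_classes <- table(unlist(sig))
  unique_per_class <- lapply(sig, function(motifs)
    motifs[n_sig_classes[motifs] == 1L])
  common <- Reduce(intersect, sig)
  list(unique_per_class = unique_per_class, common = common)
}

#' Distribution of motif presence across classes
#'
#' For the top-ranked transcripts of each class, tabulates where each
#' motif's presences fall: per motif, the fraction of transcripts
#' carrying it that belong to each class (rows sum to 1). Motifs present
#' in no transcript are omitted.
#'
#' @param class_members Named list: per class, a character vector of
#'   transcript keys (e.g. the top 25 per class).
#' @param presence Logical matrix, transcripts x motifs (TRUE when the
#'   motif occurs in the transcript's promoter).
#' @return Numeric matrix, motifs x classes, rows summing to 1.
#' @export
tfbs_distribution <- function(class_members, presence) {
  motifs <- colnames(presence)
  counts <- sapply(class_members, function(keys) {
    keys <- intersect(keys, rownames(presence))
    colSums(presence[keys, , drop = FALSE])
  })
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = length(motifs),
                     dimnames = list(motifs, names(class_members)))
  total <- rowSums(counts)
  frac <- counts[total > 0, , drop = FALSE] / total[total > 0]
  frac
}
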
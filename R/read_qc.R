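#' @name read_qc
#' @title Windowed-adaptive read quality trimming and library filters
#'
#' @description
#' Quality control for paired FASTQ libraries: a windowed-adaptive trimmer
#' that removes low-quality 5' and 3' ends (quality threshold Phred 20 by
#' default), a length rule discarding reads trimmed below about two thirds
#' of their original length, synchronized handling of read pairs, and a
#' library-level filter removing exact sequences exceeding 2% of the
#' library.
NULL

#' Phred score for a base-call accuracy
#'
#' @param accuracy Probability of a correct base call, strictly in (0, 1).
#' @return The Phred quality score, `-10 * log10(1 - accuracy)`; an
#'   accuracy of 0.99 corresponds to Phred 20.
#' @export
phred_from_accuracy <- function(accuracy) {
  if (!is.numeric(accuracy) || any(accuracy <= 0) || any(accuracy >= 1))
    stop("'accuracy' must be in (0, 1)", call. = FALSE)
  -10 * log10(1 - accuracy)
}

#' Base-call accuracy for a Phred score
#'
#' Inverse of [phred_from_accuracy()].
#'
#' @param phred Phred quality score(s), >= 0.
#' @return Accuracy fraction(s) in (0, 1].
#' @export
accuracy_from_phred <- function(phred) {
  if (!is.numeric(phred) || any(phred < 0))
    stop("'phred' must be >= 0", call. = FALSE)
  1 - 10^(-phred / 10)
}

# mean quality of every window of size w: positions i..(i+w-1)
windowed_means <- function(q, w) {
  n <- length(q)
  if (w > n) return(numeric(0))
  cs <- cumsum(c(0, q))
  (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
}

#' Trim a read by windowed mean quality from both ends
#'
#' A window of size `max(1, round(window_frac * length))` slides in from
#' the 5' end and in from the 3' end. The retained interval starts at the
#' first window (from the 5' side) whose mean quality reaches
#' `q_threshold` and ends at the last window (from the 3' side) that does.
#' Reads whose retained interval is shorter than `min_length_frac` of the
#' original length (or `min_length_abs` when given) are discarded.
#'
#' @param sequence Read sequence (single string).
#' @param qualities Integer vector of per-base Phred scores, same length
#'   as `sequence`.
#' @param q_threshold Windowed mean quality threshold (default 20).
#' @param window_frac Window size as a fraction of read length
#'   (default 0.1).
#' @param min_length_frac Minimum retained fraction before discarding
#'   (default 2/3).
#' @param min_length_abs Optional absolute minimum retained length
#'   overriding the fractional rule (e.g. 30 nt or 60 nt).
#' @return A list with `kept` (logical), and when kept: `sequence`,
#'   `qualities`, `start`, `end` (1-based positions retained).
#' @export
trim_read <- function(sequence, qualities, q_threshold = 20,
                      window_frac = 0.1, min_length_frac = 2 / 3,
                      min_length_abs = NULL) {
  n <- nchar(sequence)
  if (n == 0L) stop("empty read", call. = FALSE)
  if (length(qualities) != n)
    stop("sequence and qualities lengths differ", call. = FALSE)
  if (window_frac <= 0 || window_frac > 1)
    stop("'window_frac' must be in (0, 1]", call. = FALSE)
  w <- max(1L, as.integer(round(window_frac * n)))
  means <- windowed_means(qualities, w)
  pass <- means >= q_threshold
  if (!any(pass)) return(list(kept = FALSE))
  start <- which(pass)[1L]                 # first passing window start
  end <- max(which(pass)) + w - 1L         # last passing window end
  len <- end - start + 1L
  min_len <- if (!is.null(min_length_abs)) min_length_abs
    else min_length_frac * n
  if (len < min_len) return(list(kept = FALSE))
  list(kept = TRUE,
       sequence = substr(sequence, start, end),
       qualities = qualities[start:end],
       start = start, end = end)
}

#' Trim a read pair, keeping mates synchronized
#'
#' Both mates are trimmed with [trim_read()]; if either mate is discarded
#' the whole pair is dropped so that downstream mate files stay in step.
#'
#' @param r1,r2 Lists with `sequence` and `qualities` elements.
#' @param ... Passed to [trim_read()].
#' @return A list with `kept` and, when kept, trimmed `r1` and `r2`.
#' @export
trim_pair <- function(r1, r2, ...) {
  t1 <- trim_read(r1$sequence, r1$qualities, ...)
  t2 <- trim_read(r2$sequence, r2$qualities, ...)
  if (!t1$kept || !t2$kept) return(list(kept = FALSE))
  list(kept = TRUE, r1 = t1, r2 = t2)
}

#' Remove highly repetitive sequences from a library
#'
#' Any exact sequence whose frequency exceeds `max_frac` of the library is
#' removed entirely (all copies).
#'
#' @param sequences Character vector of read sequences.
#' @param max_frac Maximum tolerated library fraction, default 0.02.
#' @return A list with `sequences` (retained, in input order), `removed`
#'   (the offending distinct sequences) and `n_removed` (reads dropped).
#' @export
filter_repetitive <- function(sequences, max_frac = 0.02) {
  if (max_frac <= 0 || max_frac >= 1)
    stop("'max_frac' must be in (0, 1)", call. = FALSE)
  if (length(sequences) == 0L)
    return(list(sequences = character(), removed = character(),
                n_removed = 0L))
  tab <- table(sequences)
  bad <- names(tab)[tab / length(sequences) > max_frac]
  keep <- !(sequences %in% bad)
  list(sequences = sequences[keep], removed = bad,
       n_removed = sum(!keep))
}

#' Read a FASTQ file into a plain read list
#'
#' @param path FASTQ file (gzip-transparent), Phred+33 qualities.
#' @return A list of reads, each a list with `name`, `sequence` and
#'   integer `qualities`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  quals <- unname(as.character(S4Vectors::mcols(x)$qualities))
  seqs <- unname(as.character(x))
  nms <- names(x)
  lapply(seq_along(x), function(i) {
    list(name = nms[i], sequence = seqs[i],
         qualities = utf8ToInt(quals[i]) - 33L)
  })
}

#' Write a read list to a FASTQ file
#'
#' @param reads List of reads as returned by [read_fastq()].
#' @param path Output path (Phred+33).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, "", "sequence"))
  names(seqs) <- vapply(reads, `[[`, "", "name")
  quals <- Biostrings::BStringSet(vapply(reads, function(r)
    intToUtf8(r$qualities + 33L), ""))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Run the QC stage over a paired library
#'
#' Trims every pair, drops pairs failing the length rule, then removes
#' highly repetitive sequences (a pair is dropped if either trimmed mate
#' is repetitive).
#'
#' @param reads1,reads2 Mate read lists (as from [read_fastq()]), equal
#'   length.
#' @param q_threshold,window_frac,min_length_frac,min_length_abs Passed to
#'   [trim_read()].
#' @param max_repeat_frac Passed to [filter_repetitive()].
#' @return A list with `reads1`, `reads2` (surviving trimmed pairs) and a
#'   one-row `report` data frame (`pairs_in`, `pairs_after_trim`,
#'   `pairs_out`, `bases_in`, `bases_out`).
#' @export
qc_paired_library <- function(reads1, reads2, q_threshold = 20,
                              window_frac = 0.1, min_length_frac = 2 / 3,
                              min_length_abs = NULL,
                              max_repeat_frac = 0.02) {
  if (length(reads1) != length(reads2))
    stop("mate count mismatch between files", call. = FALSE)
  n_in <- length(reads1)
  bases_in <- sum(vapply(c(reads1, reads2), function(r)
    nchar(r$sequence), 0))
  out1 <- list(); out2 <- list()
  for (i in seq_len(n_in)) {
    tp <- trim_pair(reads1[[i]], reads2[[i]], q_threshold = q_threshold,
                    window_frac = window_frac,
                    min_length_frac = min_length_frac,
                    min_length_abs = min_length_abs)
    if (tp$kept) {
      r1 <- reads1[[i]]; r2 <- reads2[[i]]
      r1$sequence <- tp$r1$sequence; r1$qualities <- tp$r1$qualities
      r2$sequence <- tp$r2$sequence; r2$qualities <- tp$r2$qualities
      out1[[length(out1) + 1L]] <- r1
      out2[[length(out2) + 1L]] <- r2
    }
  }
  n_trim <- length(out1)
  # repetitive filter over both mates jointly, applied pairwise
  if (n_trim > 0L) {
    all_seq <- c(vapply(out1, `[[`, "", "sequence"),
                 vapply(out2, `[[`, "", "sequence"))
    tab <- table(all_seq)
    bad <- names(tab)[tab / length(all_seq) > max_repeat_frac]
    keep <- vapply(seq_len(n_trim), function(i)
      !(out1[[i]]$sequence %in% bad) && !(out2[[i]]$sequence %in% bad),
      logical(1))
    out1 <- out1[keep]; out2 <- out2[keep]
  }
  bases_out <- sum(vapply(c(out1, out2), function(r)
    nchar(r$sequence), 0))
  list(reads1 = out1, reads2 = out2,
       report = data.frame(pairs_in = n_in, pairs_after_trim = n_trim,
                           pairs_out = length(out1),
                           bases_in = bases_in, bases_out = bases_out))
}
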
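# Independent brute-force oracles; each is written as a plain loop so it
# stays structurally independent of the vectorized implementation paths.

# Windowed trimmer: enumerate every window of size w, take the first and
# last passing windows as the retained interval, then apply the length rule.
oracle_trim <- function(qualities, q_threshold = 20, window_frac = 0.1,
                        min_length_frac = 2 / 3) {
  n <- length(qualities)
  w <- max(1L, as.integer(round(window_frac * n)))
  starts <- integer(0); ends <- integer(0)
  for (s in seq_len(n - w + 1L)) {
    if (mean(qualities[s:(s + w - 1L)]) >= q_threshold) {
      starts <- c(starts, s)
      ends <- c(ends, s + w - 1L)
    }
  }
  if (length(starts) == 0L) return(list(kept = FALSE))
  s <- min(starts); e <- max(ends)
  if (e - s + 1L < min_length_frac * n) return(list(kept = FALSE))
  list(kept = TRUE, start = s, end = e)
}

# Benjamini-Hochberg step-up worked directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# AUC by exhaustive pair counting with half-credit for ties.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# IUPAC consensus matcher, position by position.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

oracle_scan_one_strand <- function(sequence, motif) {
  seq_chars <- strsplit(sequence, "")[[1]]
  mot_chars <- strsplit(motif, "")[[1]]
  w <- length(mot_chars); n <- length(seq_chars)
  if (w > n) return(0L)
  hits <- 0L
  for (s in seq_len(n - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(seq_chars[s + j - 1L] %in% IUPAC_SETS[[mot_chars[j]]])) {
        ok <- FALSE; break
      }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

oracle_revcomp <- function(sequence) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(sequence, "")[[1]]]), collapse = "")
}

oracle_scan <- function(sequence, motif, both_strands = TRUE) {
  hits <- oracle_scan_one_strand(sequence, motif)
  if (both_strands)
    hits <- hits + oracle_scan_one_strand(oracle_revcomp(sequence), motif)
  hits
}

# O(n^3) average-linkage agglomeration over a distance matrix, returning
# the cophenetic distance matrix (merge height between every pair).
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_h; coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Random reads for trimmer fuzzing: mixed-quality profiles.
random_read_qualities <- function(len) {
  profile <- sample(1:3, 1)
  if (profile == 1) {
    sample(2:40, len, replace = TRUE)
  } else if (profile == 2) {
    # good core with degraded ends
    q <- rep(sample(25:38, 1), len)
    k5 <- sample.int(max(1, len %/% 3), 1)
    k3 <- sample.int(max(1, len %/% 3), 1)
    q[seq_len(k5)] <- sample(2:12, k5, replace = TRUE)
    q[(len - k3 + 1):len] <- sample(2:12, k3, replace = TRUE)
    q
  } else {
    pmax(2, pmin(40, round(cumsum(rnorm(len, 0, 3)) + 25)))
  }
}

# Tiny GTF writer for annotation fixtures built in code.
write_gtf_fixture <- function(records, path) {
  # records: list of lists with transcript_id, gene_name, biotype, chrom,
  # strand, exons = matrix of 1-based closed (start, end)
  lines <- character(0)
  for (r in records) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; biotype "%s";',
      paste0(r$gene_name, "_g"), r$transcript_id, r$gene_name, r$biotype)
    lines <- c(lines, paste(r$chrom, "test", "transcript",
                            min(r$exons[, 1]), max(r$exons[, 2]), ".",
                            r$strand, ".", attrs, sep = "\t"))
    for (k in seq_len(nrow(r$exons)))
      lines <- c(lines, paste(r$chrom, "test", "exon", r$exons[k, 1],
                              r$exons[k, 2], ".", r$strand, ".", attrs,
                              sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# Phenotype labels keyed by sample for purity checks.
nepc_ad_labels <- function(metadata) {
  setNames(ifelse(metadata$phenotype_group == "NEPC", "NEPC", "AD"),
           metadata$sample_id)
}
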
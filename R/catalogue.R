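#' @name catalogue
#' @title lncRNA catalogue construction
#'
#' @description
#' Transcript-level catalogue handling: parsing Ensembl-style GTF
#' annotation into per-transcript records, restricting to the lncRNA
#' subclasses that separate neuroendocrine (NEPC) from adenocarcinoma (AD)
#' tumours (antisense, lincRNA, pseudogene), removing immunoglobulin and
#' T-cell-receptor pseudogenes, flooring low expression values, unifying
#' transcript identifiers across independently processed cohorts, and
#' dropping uncharacterized clone-style identifiers.
NULL

# Ensembl pseudogene biotypes aggregated into the single "pseudogene"
# subclass (the eight-member list; IG_*/TR_* biotypes also map here but are
# removed again by build_lncrna_catalogue).
PSEUDOGENE_BIOTYPES <- c(
  "processed_pseudogene", "unprocessed_pseudogene",
  "transcribed_unprocessed_pseudogene", "transcribed_processed_pseudogene",
  "translated_processed_pseudogene", "polymorphic_pseudogene",
  "unitary_pseudogene", "pseudogene"
)

SHORT_NCRNA_BIOTYPES <- c(
  "miRNA", "snRNA", "snoRNA", "rRNA", "misc_RNA", "Mt_rRNA", "Mt_tRNA",
  "scaRNA", "sRNA", "vaultRNA"
)

#' Map an Ensembl biotype string to a subclass group
#'
#' @param biotype Character vector of Ensembl biotype strings.
#' @param warn Warn when an unknown biotype maps to `"other"`.
#' @return Character vector of subclass groups: one of `antisense`,
#'   `lincRNA`, `pseudogene`, `processed_transcript`, `retained_intron`,
#'   `sense_intronic`, `sense_overlapping`, `three_prime_overlapping`,
#'   `protein_coding`, `short_ncRNA`, `other`.
#' @export
subclass_from_biotype <- function(biotype, warn = TRUE) {
  out <- rep("other", length(biotype))
  out[biotype == "antisense"] <- "antisense"
  out[biotype == "lincRNA"] <- "lincRNA"
  out[biotype %in% PSEUDOGENE_BIOTYPES] <- "pseudogene"
  # IG_/TR_ pseudogenes are pseudogene-derived transcripts too
  out[grepl("^(IG|TR)_.*pseudogene$", biotype)] <- "pseudogene"
  out[biotype == "processed_transcript"] <- "processed_transcript"
  out[biotype == "retained_intron"] <- "retained_intron"
  out[biotype == "sense_intronic"] <- "sense_intronic"
  out[biotype == "sense_overlapping"] <- "sense_overlapping"
  out[biotype %in% c("3prime_overlapping_ncRNA",
                     "3prime_overlapping_ncrna")] <- "three_prime_overlapping"
  out[biotype == "protein_coding"] <- "protein_coding"
  out[biotype %in% SHORT_NCRNA_BIOTYPES] <- "short_ncRNA"
  unknown <- out == "other" &
    !grepl("^(IG|TR)_", biotype) & nzchar(biotype)
  if (warn && any(unknown))
    warning(sprintf("unknown biotype(s) mapped to 'other': %s",
                    paste(unique(biotype[unknown]), collapse = ", ")),
            call. = FALSE)
  out
}

#' Read transcript annotation from a GTF file
#'
#' Parses an Ensembl-dialect GTF (attributes `transcript_id`, `gene_name`,
#' `biotype` or `gene_biotype`/`transcript_biotype`) into one record per
#' transcript with aggregated, sorted exons. Coordinates are converted to
#' 0-based half-open intervals.
#'
#' @param path Path to a GTF file.
#' @return A list with two data frames: `transcripts` (columns
#'   `transcript_id`, `gene_name`, `biotype`, `subclass_group`,
#'   `length_nt`, `chrom`, `strand`) and `exons` (columns `transcript_id`,
#'   `start`, `end`, 0-based half-open).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) {
    return(list(
      transcripts = data.frame(
        transcript_id = character(), gene_name = character(),
        biotype = character(), subclass_group = character(),
        length_nt = integer(), chrom = character(), strand = character(),
        stringsAsFactors = FALSE),
      exons = data.frame(transcript_id = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)))
  }
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  biotype <- if ("biotype" %in% names(md)) as.character(md$biotype)
    else if ("transcript_biotype" %in% names(md))
      as.character(md$transcript_biotype)
    else if ("gene_biotype" %in% names(md)) as.character(md$gene_biotype)
    else rep(NA_character_, length(gr))
  tid <- as.character(md$transcript_id)
  gname <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
    else rep(NA_character_, length(gr))

  is_exon <- type == "exon"
  declared <- unique(tid[type == "transcript"])
  exon_tids <- unique(tid[is_exon])
  missing_ex <- setdiff(declared, exon_tids)
  if (length(missing_ex) > 0L)
    stop("transcript(s) with zero exon lines: ",
         paste(missing_ex, collapse = ", "), call. = FALSE)

  ex <- data.frame(
    transcript_id = tid[is_exon],
    # GTF is 1-based closed; emit 0-based half-open
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    strand = as.character(GenomicRanges::strand(gr))[is_exon],
    biotype = biotype[is_exon],
    gene_name = gname[is_exon],
    stringsAsFactors = FALSE)
  ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]

  # per-transcript aggregation with overlap check
  split_ex <- split(ex, ex$transcript_id)
  recs <- lapply(split_ex, function(e) {
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", e$transcript_id[1L],
           call. = FALSE)
    data.frame(
      transcript_id = e$transcript_id[1L],
      gene_name = e$gene_name[1L],
      biotype = e$biotype[1L],
      length_nt = sum(e$end - e$start),
      chrom = e$chrom[1L],
      strand = e$strand[1L],
      stringsAsFactors = FALSE)
  })
  transcripts <- do.call(rbind, recs)
  rownames(transcripts) <- NULL
  transcripts$subclass_group <- subclass_from_biotype(transcripts$biotype)
  transcripts <- transcripts[, c("transcript_id", "gene_name", "biotype",
                                 "subclass_group", "length_nt", "chrom",
                                 "strand")]
  exons <- ex[, c("transcript_id", "start", "end")]
  rownames(exons) <- NULL
  list(transcripts = transcripts, exons = exons)
}

#' Restrict a transcript set to the lncRNA catalogue
#'
#' Keeps transcripts whose subclass group is `antisense`, `lincRNA` or
#' `pseudogene`; within pseudogenes, immunoglobulin and T-cell-receptor
#' biotypes (prefix `IG_`/`TR_`) are removed.
#'
#' @param transcripts Data frame of transcript records (as produced by
#'   [read_annotation()]; requires `biotype` and `subclass_group` columns).
#' @return A list with `catalogue` (the retained records) and `summary`
#'   (data frame of per-subclass counts; `n_ig_tr_removed` attribute gives
#'   the number of Ig/TCR pseudogenes removed).
#' @export
build_lncrna_catalogue <- function(transcripts) {
  if (nrow(transcripts) == 0L) stop("empty transcript set", call. = FALSE)
  keep_subclass <- transcripts$subclass_group %in%
    c("antisense", "lincRNA", "pseudogene")
  ig_tr <- grepl("^(IG|TR)_", transcripts$biotype)
  kept <- transcripts[keep_subclass & !ig_tr, , drop = FALSE]
  tab <- table(kept$subclass_group)
  summary <- data.frame(subclass_group = names(tab),
                        n = as.integer(tab), stringsAsFactors = FALSE)
  attr(summary, "n_ig_tr_removed") <- sum(keep_subclass & ig_tr)
  list(catalogue = kept, summary = summary)
}

#' Floor low expression values to zero
#'
#' Normalized expression below `floor` (strictly) is treated as a
#' quantification artifact and set to zero; values at or above the floor
#' are kept unchanged.
#'
#' @param matrix Numeric expression matrix (non-negative).
#' @param floor Flooring threshold, default 0.1.
#' @return Matrix of the same shape.
#' @export
floor_expression <- function(matrix, floor = 0.1) {
  stop_if_not_scalar_number(floor, "floor")
  if (floor < 0) stop("'floor' must be >= 0", call. = FALSE)
  if (any(matrix < 0)) stop("negative expression value", call. = FALSE)
  matrix[matrix < floor] <- 0
  matrix
}

#' Unify transcript identifiers across two cohort catalogues
#'
#' Cohorts processed independently can assign the same Ensembl transcript
#' identifier to assemblies of different length; the unified key is the
#' (identifier, length) pair, so identical pairs merge and same-identifier
#' different-length pairs stay distinct.
#'
#' @param catA,catB Transcript record data frames with `transcript_id` and
#'   `length_nt` columns.
#' @return Data frame of unified keys: `key`, `transcript_id`, `length_nt`,
#'   `in_a`, `in_b`.
#' @export
merge_cohort_keys <- function(catA, catB) {
  mk <- function(d) if (nrow(d) == 0L) character() else
    paste(d$transcript_id, d$length_nt, sep = "|")
  ka <- unique(mk(catA))
  kb <- unique(mk(catB))
  keys <- sort(unique(c(ka, kb)))
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    key = keys,
    transcript_id = vapply(parts, `[`, "", 1L),
    length_nt = as.integer(vapply(parts, `[`, "", 2L)),
    in_a = keys %in% ka,
    in_b = keys %in% kb,
    stringsAsFactors = FALSE)
}

#' Default clone-style identifier patterns
#'
#' Regular expressions matching uncharacterized clone-derived names such as
#' `RP11-123A4.2` or `AC012345.1`.
#'
#' @return Character vector of regular expressions.
#' @export
uncharacterized_patterns <- function() {
  c("^RP[0-9]+-[0-9A-Za-z]+\\.[0-9]+$",
    "^(AC|AL|AP|CT)[0-9]+\\.[0-9]+$")
}

#' Remove uncharacterized clone-style transcript names
#'
#' @param names Character vector of transcript/gene names.
#' @param patterns Regular expressions defining "uncharacterized"; defaults
#'   to [uncharacterized_patterns()].
#' @return The names that do not match any pattern.
#' @export
remove_uncharacterized <- function(names, patterns = uncharacterized_patterns()) {
  if (length(names) == 0L) return(character())
  drop <- Reduce(`|`, lapply(patterns, grepl, x = names))
  names[!drop]
}
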
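#' @name synthetic_data
#' @title Synthetic cohorts with planted, recoverable structure
#'
#' @description
#' Generators for every input the pipeline consumes: the PDX
#' transdifferentiation time series with planted temporal classes, two
#' discovery cohorts and a validation-style second cohort with planted
#' NEPC/AD signature transcripts, an outcome cohort with
#' expression-linked metastasis hazards in the treated arm, promoter
#' sequences with planted motifs, paired FASTQ reads, and microarray
#' probe maps. Alongside each data set a truth table records what was
#' planted, so parameter recovery can be measured exactly. All
#' generators are deterministic given the configuration seed.
#'
#' @details
#' Expression noise is multiplicative log2-normal around the planted
#' stage/group means, matching FPKM-like positively skewed data and
#' making log2 fold changes Gaussian. Event times are exponential with
#' log hazard linear in a standardized latent risk shared by the planted
#' predictive transcripts.
NULL

TEMPORAL_CLASSES <- c("I_Deactivated", "II_Activated", "III_Persistent",
                      "IV_Transient")

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data module with validated
#' defaults.
#'
#' @param seed Integer seed; the same configuration always produces
#'   byte-identical outputs.
#' @param n_transcripts Total transcripts simulated.
#' @param n_planted_per_class Planted transcripts per temporal class.
#' @param class_effect_fold Linear fold change between consecutive PDX
#'   time points for planted classes (default 4).
#' @param noise_sd_log2 SD of the multiplicative log2-normal measurement
#'   noise (default 0.25).
#' @param cohort_sizes Named list `A`, `B` of named sample counts per
#'   phenotype group. Cohort A needs `AD_NAIVE`, `NHT`, `CRPC`, `NEPC`;
#'   cohort B needs `AD`, `NEPC`.
#' @param signature_size Planted NEPC-vs-AD discriminative transcripts
#'   (half up-, half down-regulated).
#' @param signature_fold Fold separating NEPC from AD for signature
#'   transcripts in both cohorts (default 16).
#' @param pdx_replicates Replicates at the terminal PDX stages (AD and
#'   NEPC); the post-castration stages always have one sample per week.
#' @param outcome_n Samples in the outcome cohort.
#' @param outcome_hazard_fold Hazard ratio per SD of the latent risk in
#'   ADT-treated samples (>= 1; 1 disables the link).
#' @param outcome_planted,outcome_null Predictive and null transcripts
#'   in the outcome cohort.
#' @param patient_sd_log2 Between-patient SD of log2 expression in the
#'   outcome cohort.
#' @param base_hazard Baseline event rate per month (default
#'   `log(2)/48`: a 48-month median time to metastasis).
#' @param treated_frac Fraction of outcome samples receiving ADT.
#' @param censor_frac Fraction of samples censored before their event or
#'   administrative follow-up.
#' @param followup_range Administrative follow-up window in months
#'   (default 120 to 240, so uncensored non-events satisfy the ten-year
#'   control rule).
#' @param read_length Read length for FASTQ generation.
#' @param n_read_pairs Read pairs per library.
#' @param base_error_profile Per-position base error probabilities
#'   (length `read_length`); default a uniform 0.001 (Phred 30).
#' @param dup_frac Fraction of exact duplicate reads planted.
#' @param low_qual_tail_frac Fraction of reads given a low-quality
#'   (Phred 2) 3' tail spanning the last 20% of cycles.
#' @param promoter_length,n_promoters_per_class Promoter simulation
#'   dimensions.
#' @param probe_length Probe set region width in nt.
#' @param containment_frac Fraction of probes placed fully inside an
#'   exon (default 0.87).
#' @return A validated list of class `netdlnc_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_transcripts = 1000L,
    n_planted_per_class = 50L,
    class_effect_fold = 4,
    noise_sd_log2 = 0.25,
    cohort_sizes = list(
      A = c(AD_NAIVE = 12L, NHT = 8L, CRPC = 8L, NEPC = 4L),
      B = c(AD = 30L, NEPC = 7L)),
    signature_size = 30L,
    signature_fold = 16,
    pdx_replicates = 2L,
    outcome_n = 200L,
    outcome_hazard_fold = 3,
    outcome_planted = 5L,
    outcome_null = 20L,
    patient_sd_log2 = 1,
    base_hazard = log(2) / 48,
    treated_frac = 0.5,
    censor_frac = 0.2,
    followup_range = c(120, 240),
    read_length = 100L,
    n_read_pairs = 100L,
    base_error_profile = NULL,
    dup_frac = 0,
    low_qual_tail_frac = 0,
    promoter_length = 500L,
    n_promoters_per_class = 25L,
    probe_length = 25L,
    containment_frac = 0.87) {
  cfg <- list(seed = as.integer(seed), n_transcripts = n_transcripts,
              n_planted_per_class = n_planted_per_class,
              class_effect_fold = class_effect_fold,
              noise_sd_log2 = noise_sd_log2, cohort_sizes = cohort_sizes,
              signature_size = signature_size,
              signature_fold = signature_fold,
              pdx_replicates = pdx_replicates, outcome_n = outcome_n,
              outcome_hazard_fold = outcome_hazard_fold,
              outcome_planted = outcome_planted,
              outcome_null = outcome_null,
              patient_sd_log2 = patient_sd_log2,
              base_hazard = base_hazard, treated_frac = treated_frac,
              censor_frac = censor_frac, followup_range = followup_range,
              read_length = read_length, n_read_pairs = n_read_pairs,
              base_error_profile = base_error_profile %||%
                rep(0.001, read_length),
              dup_frac = dup_frac,
              low_qual_tail_frac = low_qual_tail_frac,
              promoter_length = promoter_length,
              n_promoters_per_class = n_promoters_per_class,
              probe_length = probe_length,
              containment_frac = containment_frac)
  counts <- c(cfg$n_transcripts, cfg$n_planted_per_class,
              cfg$signature_size, cfg$outcome_n, cfg$read_length,
              cfg$n_read_pairs, cfg$promoter_length,
              cfg$n_promoters_per_class, cfg$probe_length)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (cfg$noise_sd_log2 < 0)
    stop("'noise_sd_log2' must be >= 0", call. = FALSE)
  if (cfg$pdx_replicates < 1L)
    stop("zero replicates requested for terminal PDX stages",
         call. = FALSE)
  if (cfg$outcome_hazard_fold < 1)
    stop("'outcome_hazard_fold' must be >= 1", call. = FALSE)
  if (any(cfg$followup_range <= 0) || diff(cfg$followup_range) < 0)
    stop("non-positive follow-up horizon", call. = FALSE)
  if (4L * cfg$n_planted_per_class + cfg$signature_size >
        cfg$n_transcripts)
    stop("planted transcripts exceed n_transcripts", call. = FALSE)
  if (length(cfg$base_error_profile) != cfg$read_length)
    stop("base_error_profile length must equal read_length",
         call. = FALSE)
  need_a <- c("AD_NAIVE", "NHT", "CRPC", "NEPC")
  if (!all(need_a %in% names(cfg$cohort_sizes$A)))
    stop("cohort A sizes must cover ",
         paste(need_a, collapse = ", "), call. = FALSE)
  if (!all(c("AD", "NEPC") %in% names(cfg$cohort_sizes$B)))
    stop("cohort B sizes must cover AD, NEPC", call. = FALSE)
  structure(cfg, class = "netdlnc_config")
}

# planted role per transcript: the temporal classes, then the signature
# halves, then null; roles partition the transcript list
planted_roles <- function(config) {
  n <- config$n_transcripts
  k <- config$n_planted_per_class
  roles <- rep("null", n)
  idx <- 1L
  for (cls in TEMPORAL_CLASSES) {
    roles[idx:(idx + k - 1L)] <- cls
    idx <- idx + k
  }
  half <- config$signature_size %/% 2L
  if (config$signature_size > 0L) {
    roles[idx:(idx + half - 1L)] <- "signature_up"
    roles[(idx + half):(idx + config$signature_size - 1L)] <-
      "signature_down"
  }
  data.frame(transcript_key = sprintf("TX%05d", seq_len(n)),
             planted_role = roles, stringsAsFactors = FALSE)
}

# base (AD-stage) expression level per transcript, FPKM-like
base_levels <- function(n) 2^rnorm(n, mean = 3, sd = 1)

noise_factor <- function(n, sd_log2) 2^rnorm(n, 0, sd_log2)

#' Generate the PDX transdifferentiation time series
#'
#' Six samples by default: two AD replicates, one post-castration sample
#' at week 8 and one at week 12, and two relapsed NEPC replicates.
#' Planted transcripts follow their class pattern across the stage means
#' (fold `f = class_effect_fold`, base level `b`):
#' I `(b, b/f, b/f^2)`; II `(b, b, f*b)`; III `(b, f*b, f^2*b)`;
#' IV `(b, f*b, b)`; null transcripts are flat.
#'
#' @param config A [simulation_config()].
#' @return A list with `matrix` (transcripts x samples), `metadata`
#'   (`sample_id`, `cohort`, `phenotype_group`) and `truth`
#'   (`transcript_key`, `planted_role`).
#' @export
generate_pdx_timeseries <- function(config) {
  stopifnot(inherits(config, "netdlnc_config"))
  set.seed(config$seed + 101L)
  truth <- planted_roles(config)
  n <- config$n_transcripts
  f <- config$class_effect_fold
  b <- base_levels(n)
  stage_mult <- cbind(AD = rep(1, n), postTX = rep(1, n),
                      NEPC = rep(1, n))
  for (cls in TEMPORAL_CLASSES) {
    i <- truth$planted_role == cls
    stage_mult[i, ] <- matrix(switch(cls,
      I_Deactivated = c(1, 1 / f, 1 / f^2),
      II_Activated = c(1, 1, f),
      III_Persistent = c(1, f, f^2),
      IV_Transient = c(1, f, 1)), nrow = sum(i), ncol = 3,
      byrow = TRUE)
  }
  reps <- config$pdx_replicates
  samples <- c(paste0("PDX_AD_", seq_len(reps)), "PDX_POSTTX_8W",
               "PDX_POSTTX_12W", paste0("PDX_NEPC_", seq_len(reps)))
  stages <- c(rep("AD", reps), "postTX", "postTX", rep("NEPC", reps))
  m <- sapply(stages, function(st)
    b * stage_mult[, st] * noise_factor(n, config$noise_sd_log2))
  colnames(m) <- samples
  rownames(m) <- truth$transcript_key
  metadata <- data.frame(
    sample_id = samples, cohort = "PDX",
    phenotype_group = c(rep("PDX_AD", reps), "PDX_POSTTX_8W",
                        "PDX_POSTTX_12W", rep("PDX_NEPC", reps)),
    stringsAsFactors = FALSE)
  list(matrix = m, metadata = metadata, truth = truth)
}

# group multiplier for one planted role in the clinical cohorts
clinical_multiplier <- function(role, group, f, sig_fold) {
  switch(role,
    I_Deactivated = if (group %in% c("NHT", "CRPC", "NEPC")) 1 / f else 1,
    II_Activated = if (group == "NEPC") f else 1,
    III_Persistent = if (group == "NEPC") f else 1,
    IV_Transient = if (group == "NHT") f else 1,
    signature_up = if (group == "NEPC") sig_fold else 1,
    signature_down = if (group == "NEPC") 1 / sig_fold else 1,
    1)
}

#' Generate the two clinical discovery cohorts
#'
#' Cohort A carries the four phenotype groups (AD_NAIVE, NHT, CRPC,
#' NEPC), cohort B the two terminal ones (AD, NEPC). Planted temporal
#' classes echo their expected clinical deregulation (I down in
#' NHT/CRPC/NEPC vs AD; II and III up in NEPC; IV up in NHT and back
#' down in NEPC); signature transcripts separate NEPC from AD by
#' `signature_fold` in both cohorts; null transcripts are flat.
#'
#' @param config A [simulation_config()].
#' @return A list with `A` and `B` (each `matrix` + `metadata`) and
#'   `truth`.
#' @export
generate_clinical_cohorts <- function(config) {
  stopifnot(inherits(config, "netdlnc_config"))
  set.seed(config$seed + 202L)
  truth <- planted_roles(config)
  n <- config$n_transcripts
  b <- base_levels(n)
  make_cohort <- function(cohort_name, sizes) {
    groups <- rep(names(sizes), sizes)
    samples <- sprintf("%s_%s_%02d", cohort_name, groups,
                       unlist(lapply(sizes, seq_len)))
    m <- matrix(0, n, length(samples),
                dimnames = list(truth$transcript_key, samples))
    for (j in seq_along(samples)) {
      mult <- vapply(truth$planted_role, clinical_multiplier, 0,
                     group = groups[j], f = config$class_effect_fold,
                     sig_fold = config$signature_fold)
      m[, j] <- b * mult * noise_factor(n, config$noise_sd_log2)
    }
    metadata <- data.frame(
      sample_id = samples, cohort = cohort_name,
      phenotype_group = groups, adt_treated = groups == "NHT",
      time_to_metastasis_months = NA_real_, metastasis_event = NA,
      followup_months = NA_real_, stringsAsFactors = FALSE)
    list(matrix = m, metadata = metadata)
  }
  list(A = make_cohort("A", config$cohort_sizes$A),
       B = make_cohort("B", config$cohort_sizes$B),
       truth = truth)
}

#' Generate the outcome cohort with treatment-linked hazards
#'
#' Each sample carries a latent standard-normal risk score. The planted
#' predictive transcripts express `patient_sd_log2 * risk` (in log2
#' units, plus measurement noise); in ADT-treated samples the metastasis
#' hazard is `base_hazard * outcome_hazard_fold^risk`, while untreated
#' samples keep the baseline hazard, so their outcomes are independent
#' of expression. Event times are exponential; a `censor_frac` fraction
#' of samples is censored uniformly before their event, and everyone
#' else is followed to an administrative horizon drawn from
#' `followup_range` (metastasis-free samples therefore have at least ten
#' years of follow-up).
#'
#' @param config A [simulation_config()].
#' @return A list with `matrix` (planted + null transcripts x samples),
#'   `metadata` (`sample_id`, `cohort`, `phenotype_group`,
#'   `adt_treated`, `time_to_metastasis_months`, `metastasis_event`,
#'   `followup_months`) and `truth` (per-transcript `planted_role`:
#'   `predictive` or `null`).
#' @export
generate_outcome_cohort <- function(config) {
  stopifnot(inherits(config, "netdlnc_config"))
  set.seed(config$seed + 303L)
  n_s <- config$outcome_n
  n_pred <- config$outcome_planted
  n_null <- config$outcome_null
  samples <- sprintf("P%04d", seq_len(n_s))
  keys <- c(sprintf("OTX_PRED%02d", seq_len(n_pred)),
            sprintf("OTX_NULL%02d", seq_len(n_null)))
  risk <- rnorm(n_s)
  b <- base_levels(n_pred + n_null)
  m <- matrix(0, n_pred + n_null, n_s,
              dimnames = list(keys, samples))
  for (i in seq_len(n_pred + n_null)) {
    link <- if (i <= n_pred) config$patient_sd_log2 * risk else
      rnorm(n_s, 0, config$patient_sd_log2)
    m[i, ] <- b[i] * 2^(link +
                          rnorm(n_s, 0, config$noise_sd_log2))
  }
  treated <- runif(n_s) < config$treated_frac
  rate <- ifelse(treated,
                 config$base_hazard * config$outcome_hazard_fold^risk,
                 config$base_hazard)
  t_event <- rexp(n_s, rate)
  horizon <- runif(n_s, config$followup_range[1],
                   config$followup_range[2])
  censored_early <- runif(n_s) < config$censor_frac
  event <- !censored_early & t_event <= horizon
  followup <- ifelse(censored_early,
                     runif(n_s) * pmin(t_event, horizon),
                     pmin(t_event, horizon))
  metadata <- data.frame(
    sample_id = samples, cohort = "OUTCOME", phenotype_group = "AD",
    adt_treated = treated,
    time_to_metastasis_months = ifelse(event, t_event, NA_real_),
    metastasis_event = event, followup_months = followup,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    transcript_key = keys,
    planted_role = rep(c("predictive", "null"), c(n_pred, n_null)),
    stringsAsFactors = FALSE)
  list(matrix = m, metadata = metadata, truth = truth)
}

IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# one concrete realization of an IUPAC consensus
realize_motif <- function(motif) {
  letters <- strsplit(motif, "")[[1]]
  paste(vapply(letters, function(l)
    sample(IUPAC_BASES[[l]], 1L), ""), collapse = "")
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), "")
}

#' Generate promoter sequences with planted motifs
#'
#' Random background sequences per class, with one realization of each
#' motif inserted (overwriting the background) at a per-class rate. The
#' returned hit table holds the exact scan counts of the emitted
#' sequences, so planted structure is recoverable by construction.
#'
#' @param config A [simulation_config()].
#' @param motifs Named character vector of IUPAC consensus strings.
#' @param insert_rate Named list or numeric: per class, the probability
#'   that a sequence receives one planted insertion of a motif. A single
#'   number per class applies to every motif; a named numeric vector sets
#'   per-motif rates. Classes default to the four temporal classes at
#'   rate 0.
#' @param both_strands Count reverse-complement matches too.
#' @return A list with `sequences` (named list of character vectors per
#'   class) and `hits` (data frame `class_label`, `motif_id`, `x`,
#'   `n_sequences`, `n_positions`).
#' @export
generate_promoters_and_hits <- function(config, motifs,
                                        insert_rate = NULL,
                                        both_strands = TRUE) {
  stopifnot(inherits(config, "netdlnc_config"))
  if (length(motifs) == 0L) stop("motifs must be non-empty",
                                 call. = FALSE)
  if (is.null(names(motifs)))
    names(motifs) <- paste0("motif_", seq_along(motifs))
  motifs <- vapply(motifs, check_iupac, "")
  if (is.null(insert_rate))
    insert_rate <- setNames(rep(0, length(TEMPORAL_CLASSES)),
                            TEMPORAL_CLASSES)
  set.seed(config$seed + 404L)
  L <- config$promoter_length
  sequences <- list()
  hit_rows <- list()
  for (cls in names(insert_rate)) {
    seqs <- random_dna(config$n_promoters_per_class, L)
    cls_rate <- insert_rate[[cls]]
    for (mi in seq_along(motifs)) {
      w <- nchar(motifs[mi])
      rate <- if (length(cls_rate) == 1L && is.null(names(cls_rate)))
        cls_rate else (cls_rate[names(motifs)[mi]] %|NA|% 0)
      plant <- runif(length(seqs)) < rate
      for (si in which(plant)) {
        pos <- sample.int(L - w + 1L, 1L)
        substr(seqs[si], pos, pos + w - 1L) <- realize_motif(motifs[mi])
      }
    }
    sequences[[cls]] <- seqs
    for (mi in seq_along(motifs)) {
      w <- nchar(motifs[mi])
      x <- sum(scan_consensus(seqs, motifs[mi], both_strands))
      n_pos <- length(seqs) * (L - w + 1L) * (1L + both_strands)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        class_label = cls, motif_id = names(motifs)[mi], x = x,
        n_sequences = length(seqs), n_positions = n_pos,
        stringsAsFactors = FALSE)
    }
  }
  list(sequences = sequences, hits = do.call(rbind, hit_rows))
}

#' Generate a paired synthetic FASTQ library
#'
#' Random sequences with Phred+33 qualities derived from the per-position
#' base error profile, optional planted low-quality 3' tails and exact
#' duplicate reads.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, `reads_1.fastq` and
#'   `reads_2.fastq` are written there.
#' @return A list with `reads1`, `reads2` (read lists as in
#'   [read_fastq()]) and, when written, `path1`, `path2`.
#' @export
generate_fastq <- function(config, dir = NULL) {
  stopifnot(inherits(config, "netdlnc_config"))
  set.seed(config$seed + 505L)
  n <- config$n_read_pairs
  L <- config$read_length
  quals <- pmin(41L, pmax(2L, as.integer(round(
    -10 * log10(config$base_error_profile)))))
  make_mate <- function(mate) {
    seqs <- random_dna(n, L)
    n_dup <- floor(config$dup_frac * n)
    if (n_dup > 0L && n > 1L)
      seqs[1L + seq_len(n_dup)] <- seqs[1L]
    tail_len <- max(1L, as.integer(round(0.2 * L)))
    low_tail <- runif(n) < config$low_qual_tail_frac
    lapply(seq_len(n), function(i) {
      q <- quals
      if (low_tail[i]) q[(L - tail_len + 1L):L] <- 2L
      list(name = sprintf("read%05d/%d", i, mate),
           sequence = seqs[i], qualities = q)
    })
  }
  reads1 <- make_mate(1L)
  reads2 <- make_mate(2L)
  out <- list(reads1 = reads1, reads2 = reads2)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$path1 <- file.path(dir, "reads_1.fastq")
    out$path2 <- file.path(dir, "reads_2.fastq")
    write_fastq(reads1, out$path1)
    write_fastq(reads2, out$path2)
  }
  out
}

#' Generate synthetic transcript models
#'
#' Simple multi-exon transcript structures on one chromosome, spaced so
#' that transcripts never overlap; used as the substrate for probe-map
#' simulation and annotation round-trips.
#'
#' @param config A [simulation_config()].
#' @param n Number of transcripts (default 122).
#' @param n_exons Exons per transcript.
#' @param exon_length,intron_length Exon/intron sizes in nt.
#' @return A list with `transcripts` and `exons` data frames matching
#'   [read_annotation()] output.
#' @export
generate_transcript_models <- function(config, n = 122L, n_exons = 3L,
                                       exon_length = 200L,
                                       intron_length = 500L) {
  stopifnot(inherits(config, "netdlnc_config"))
  set.seed(config$seed + 707L)
  span <- n_exons * exon_length + (n_exons - 1L) * intron_length
  spacing <- span + 10000L
  tx <- sprintf("SYNTX%04d", seq_len(n))
  exon_rows <- list()
  for (i in seq_len(n)) {
    start0 <- (i - 1L) * spacing
    starts <- start0 + (seq_len(n_exons) - 1L) *
      (exon_length + intron_length)
    exon_rows[[i]] <- data.frame(
      transcript_id = tx[i], chrom = "chr1", start = starts,
      end = starts + exon_length, stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, exon_rows)
  transcripts <- data.frame(
    transcript_id = tx, gene_name = paste0("SYNG", seq_len(n)),
    biotype = "lincRNA", subclass_group = "lincRNA",
    length_nt = n_exons * exon_length, chrom = "chr1", strand = "+",
    stringsAsFactors = FALSE)
  list(transcripts = transcripts, exons = exons)
}

#' Generate a probe map over a transcript catalogue
#'
#' For a `containment_frac` fraction of transcripts the probe lies fully
#' inside an exon; the rest straddle an exon 3' boundary (extending into
#' the intron or past the transcript), so they fail the containment
#' liftover rule. Containment truth is recorded per probe.
#'
#' @param config A [simulation_config()].
#' @param models Transcript models (list with `transcripts` and `exons`
#'   as from [generate_transcript_models()] or [read_annotation()]).
#' @return A list with `probes` (data frame `probe_id`, `chrom`,
#'   `start`, `end`) and `truth` (`probe_id`, `transcript_id`,
#'   `contained`). Transcripts without exons are skipped with a warning.
#' @export
generate_probe_map <- function(config, models) {
  stopifnot(inherits(config, "netdlnc_config"))
  transcripts <- models$transcripts
  exons <- models$exons
  if (nrow(transcripts) == 0L) stop("empty catalogue", call. = FALSE)
  set.seed(config$seed + 606L)
  plen <- config$probe_length
  rows <- list(); truth <- list()
  for (i in seq_len(nrow(transcripts))) {
    tid <- transcripts$transcript_id[i]
    ex <- exons[exons$transcript_id == tid, , drop = FALSE]
    if (nrow(ex) == 0L) {
      warning("transcript without exons skipped: ", tid, call. = FALSE)
      next
    }
    ex <- ex[ex$end - ex$start >= plen, , drop = FALSE]
    if (nrow(ex) == 0L) {
      warning("no exon long enough for a probe in ", tid, call. = FALSE)
      next
    }
    e <- ex[sample.int(nrow(ex), 1L), ]
    contained <- runif(1) < config$containment_frac
    if (contained) {
      start <- e$start + sample.int(e$end - e$start - plen + 1L, 1L) - 1L
    } else {
      # straddle the exon 3' boundary: half in, half out
      start <- e$end - plen %/% 2L
    }
    pid <- sprintf("PSR%05d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = pid, chrom = transcripts$chrom[i], start = start,
      end = start + plen, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      probe_id = pid, transcript_id = tid, contained = contained,
      stringsAsFactors = FALSE)
  }
  list(probes = do.call(rbind, rows), truth = do.call(rbind, truth))
}
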
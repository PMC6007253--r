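#' @name signature
#' @title Cross-cohort NEPC expression signature
#'
#' @description
#' Derives a cohort-robust expression signature separating NEPC from AD
#' tumours: per cohort, transcripts are ranked by the standard deviation
#' of their log2 expression and the top fifth percentile retained
#' (uncharacterized clone identifiers removed first); the per-cohort lists
#' are intersected and each cohort re-clustered on the intersection with
#' unsupervised hierarchical clustering (Pearson distance, average
#' linkage). Separation is quantified by the purity of the two-cluster
#' cut against the NEPC/AD phenotype. Signature members are then ranked
#' by NEPC-vs-AD fold change, requiring cross-cohort concordance and a
#' greater than 10-fold magnitude for the headline candidates.
NULL

#' Select the top variance percentile of transcripts
#'
#' Ranks transcripts by the sample standard deviation of
#' `log2(expression + pseudocount)` across samples and returns the top
#' `percentile` percent (`ceiling(percentile/100 * n)` transcripts). Ties
#' at the boundary are broken by lexicographic key order, so the result
#' is deterministic.
#'
#' @param matrix Expression matrix.
#' @param percentile Percent of transcripts to keep (default 5).
#' @param pseudocount Log-transform pseudocount (default 0.1).
#' @return Character vector of transcript keys.
#' @export
top_variance_percentile <- function(matrix, percentile = 5,
                                    pseudocount = 0.1) {
  validate_expression(matrix)
  if (nrow(matrix) < 20L)
    stop("need >= 20 transcripts to take a variance percentile",
         call. = FALSE)
  sds <- apply(log2p(matrix, pseudocount), 1, sd)
  k <- ceiling(percentile / 100 * nrow(matrix))
  ord <- order(-sds, rownames(matrix))
  rownames(matrix)[ord[seq_len(k)]]
}

#' Row-standardize a matrix with clipping
#'
#' Per row: subtract the mean, divide by the sample standard deviation and
#' clip the result to \[-2, 2\]. Constant rows map to all zero.
#'
#' @param matrix Numeric matrix.
#' @return Matrix of the same shape with values in \[-2, 2\].
#' @export
scale_rows <- function(matrix) {
  mu <- rowMeans(matrix)
  sds <- apply(matrix, 1, sd)
  z <- sweep(matrix, 1, mu, "-")
  nz <- sds > 0
  z[nz, ] <- sweep(z[nz, , drop = FALSE], 1, sds[nz], "/")
  z[!nz, ] <- 0
  pmin(pmax(z, -2), 2)
}

#' Agglomerative clustering of samples
#'
#' Unsupervised hierarchical clustering over the columns of an expression
#' matrix, with either one-minus-Pearson-correlation distance and average
#' linkage (the sequencing-cohort recipe) or Euclidean distance with Ward
#' linkage (the microarray-cohort recipe).
#'
#' @param matrix Numeric matrix; columns are clustered.
#' @param distance `"one_minus_pearson"` or `"euclidean"`.
#' @param linkage `"average"` or `"ward"` (ward.D2).
#' @return A list with `tree` (an `hclust` object), `distance`, `linkage`
#'   and `cut(k)` labels available via [cut_clusters()]. Zero-variance
#'   columns are dropped with a warning under the Pearson distance.
#' @export
hcluster <- function(matrix, distance = c("one_minus_pearson",
                                          "euclidean"),
                     linkage = c("average", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (ncol(matrix) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (distance == "one_minus_pearson") {
    csd <- apply(matrix, 2, sd)
    if (any(csd == 0)) {
      warning("dropping zero-variance column(s) under Pearson distance: ",
              paste(colnames(matrix)[csd == 0], collapse = ", "),
              call. = FALSE)
      matrix <- matrix[, csd > 0, drop = FALSE]
      if (ncol(matrix) < 2L)
        stop("fewer than 2 usable samples after dropping zero-variance columns",
             call. = FALSE)
    }
    d <- as.dist(1 - cor(matrix, method = "pearson"))
  } else {
    d <- dist(t(matrix), method = "euclidean")
  }
  method <- if (linkage == "average") "average" else "ward.D2"
  list(tree = hclust(d, method = method), distance = distance,
       linkage = linkage)
}

#' Cut a clustering result into k groups
#'
#' @param clustering Result of [hcluster()].
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels per sample.
#' @export
cut_clusters <- function(clustering, k) {
  cutree(clustering$tree, k = k)
}

# max agreement between cluster labels and a binary phenotype
cluster_purity <- function(clusters, phenotype) {
  phenotype <- phenotype[names(clusters)]
  tab <- table(clusters, phenotype)
  sum(apply(tab, 1, max)) / length(clusters)
}

#' Derive the cross-cohort NEPC signature
#'
#' @param matrixA,matrixB Expression matrices for the two discovery
#'   cohorts on a shared key space (see [merge_cohort_keys()]).
#' @param labelsA,labelsB Named character vectors (per sample) with values
#'   `"NEPC"` or `"AD"`-like; used only for the purity report.
#' @param percentile Variance percentile per cohort (default 5).
#' @param gene_names Optional named character vector mapping transcript
#'   keys to gene names; when supplied, uncharacterized-name removal and
#'   the intersection operate at gene-name level. Default identity.
#' @param pseudocount Log-transform pseudocount.
#' @return A list with `signature` (keys in the intersection), `perA`,
#'   `perB` (per-cohort top-percentile keys after uncharacterized
#'   removal), and `purity` (named numeric, k = 2 cut agreement with the
#'   phenotype per cohort; `NA` when the signature has < 2 members).
#' @export
derive_signature <- function(matrixA, labelsA, matrixB, labelsB,
                             percentile = 5, gene_names = NULL,
                             pseudocount = 0.1) {
  name_of <- function(keys) {
    if (is.null(gene_names)) keys else unname(gene_names[keys])
  }
  top_named <- function(m) {
    keys <- top_variance_percentile(m, percentile, pseudocount)
    kept_names <- remove_uncharacterized(unique(name_of(keys)))
    keys[name_of(keys) %in% kept_names]
  }
  topA <- top_named(matrixA)
  topB <- top_named(matrixB)
  sig_names <- intersect(name_of(topA), name_of(topB))
  signature <- sort(unique(c(topA[name_of(topA) %in% sig_names],
                             topB[name_of(topB) %in% sig_names])))
  signature <- signature[signature %in% rownames(matrixA) &
                           signature %in% rownames(matrixB)]
  if (length(signature) == 0L)
    warning("empty signature: cohorts share no top-variance transcripts",
            call. = FALSE)
  purity <- c(A = NA_real_, B = NA_real_)
  if (length(signature) >= 2L) {
    recluster <- function(m, labels) {
      scaled <- scale_rows(log2p(m[signature, , drop = FALSE],
                                 pseudocount))
      cl <- hcluster(scaled, "one_minus_pearson", "average")
      cluster_purity(cut_clusters(cl, 2), labels)
    }
    purity["A"] <- recluster(matrixA, labelsA)
    purity["B"] <- recluster(matrixB, labelsB)
  }
  list(signature = signature, perA = topA, perB = topB, purity = purity)
}

#' Rank signature transcripts by cross-cohort fold change
#'
#' Computes the NEPC-vs-AD fold change per cohort for each signature
#' transcript and flags those with concordant direction and at least
#' `magnitude_fold` change in both cohorts.
#'
#' @param matrixA,matrixB Expression matrices.
#' @param metadataA,metadataB Data frames with `sample_id` and
#'   `phenotype_group`; NEPC samples vs the AD-like reference
#'   (`AD` or `AD_NAIVE`).
#' @param signature Character vector of transcript keys.
#' @param magnitude_fold Magnitude threshold (default 10).
#' @param pseudocount Ratio pseudocount.
#' @return Data frame ordered by decreasing minimum cross-cohort
#'   magnitude: `transcript_key`, `fc_a`, `fc_b`, `concordant`,
#'   `flagged`.
#' @export
rank_signature <- function(matrixA, metadataA, matrixB, metadataB,
                           signature, magnitude_fold = 10,
                           pseudocount = 0.1) {
  if (length(signature) == 0L) stop("empty signature", call. = FALSE)
  fc_cohort <- function(m, md) {
    ref <- if ("AD" %in% md$phenotype_group) "AD" else "AD_NAIVE"
    ids_a <- md$sample_id[md$phenotype_group == ref]
    ids_b <- md$sample_id[md$phenotype_group == "NEPC"]
    ma <- rowMeans(m[signature, ids_a, drop = FALSE])
    mb <- rowMeans(m[signature, ids_b, drop = FALSE])
    (mb + pseudocount) / (ma + pseudocount)
  }
  fa <- fc_cohort(matrixA, metadataA)
  fb <- fc_cohort(matrixB, metadataB)
  magnitude <- function(fc) pmax(fc, 1 / fc)
  concordant <- (fa > 1 & fb > 1) | (fa < 1 & fb < 1)
  flagged <- concordant & magnitude(fa) >= magnitude_fold &
    magnitude(fb) >= magnitude_fold
  out <- data.frame(transcript_key = signature, fc_a = fa, fc_b = fb,
                    concordant = concordant, flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-pmin(magnitude(fa), magnitude(fb)), out$transcript_key), ,
      drop = FALSE]
}

#' Top three principal components of a sample set
#'
#' Principal component analysis over samples (columns) of an expression
#' matrix, returning the leading component scores for visual inspection.
#'
#' @param matrix Numeric matrix (features x samples).
#' @return A list with `scores` (samples x up to 3 components) and
#'   `variance_fraction` (per returned component).
#' @export
pca_top3 <- function(matrix) {
  p <- prcomp(t(matrix), center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(p$x))
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       variance_fraction = vf[seq_len(k)])
}
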
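test_that("top variance percentile selects planted variable rows", {
  set.seed(41)
  m <- matrix(5, 100, 10,
              dimnames = list(sprintf("t%03d", 1:100), paste0("s", 1:10)))
  m <- m * 2^matrix(rnorm(1000, 0, 0.05), 100, 10)
  planted <- sprintf("t%03d", 96:100)
  m[planted, 1:5] <- m[planted, 1:5] * 32
  keys <- top_variance_percentile(m)
  expect_length(keys, 5L)              # ceiling(5% of 100)
  expect_setequal(keys, planted)
  # constant rows are never selected while any variable row exists
  m2 <- rbind(m, const = rep(3, 10))
  expect_false("const" %in% top_variance_percentile(m2))
  expect_error(top_variance_percentile(m[1:10, ]), ">= 20")
})

test_that("row scaling centres, standardizes and clips to [-2, 2]", {
  m <- rbind(a = c(1, 2, 3), b = c(7, 7, 7))
  s <- scale_rows(m)
  expect_equal(unname(s["a", ]), c(-1, 0, 1))     # sample SD = 1
  expect_equal(unname(s["b", ]), c(0, 0, 0))      # constant row
  # a strong outlier exceeds 2 SDs and is clipped to the range edge
  out_row <- matrix(c(rep(0, 9), 100), 1, 10)
  expect_equal(max(abs(scale_rows(out_row))), 2)
  # rows have mean zero before clipping
  set.seed(42)
  r <- matrix(rnorm(50), 5, 10)
  pre <- sweep(r, 1, rowMeans(r), "-") / apply(r, 1, sd)
  expect_equal(rowMeans(pre), rep(0, 5))
  expect_true(all(abs(scale_rows(r)) <= 2))
})

test_that("average-linkage Pearson clustering matches a brute-force oracle", {
  set.seed(43)
  for (i in 1:50) {
    m <- matrix(rnorm(8 * 10), 8, 10,
                dimnames = list(NULL, paste0("s", 1:10)))
    fit <- hcluster(m, "one_minus_pearson", "average")
    d <- as.dist(1 - cor(m))
    coph_oracle <- oracle_upgma_cophenetic(d)
    coph_pkg <- as.matrix(stats::cophenetic(fit$tree))
    dimnames(coph_oracle) <- dimnames(coph_pkg)
    expect_equal(coph_pkg, coph_oracle, tolerance = 1e-10)
    # merge heights are monotone for average linkage on a metric
    expect_true(all(diff(fit$tree$height) >= -1e-12))
  }
})

test_that("clustering recovers separated groups and handles edge cases", {
  set.seed(44)
  blob <- cbind(matrix(rnorm(40 * 6, 0), 40, 6),
                matrix(rnorm(40 * 6, 6), 40, 6))
  colnames(blob) <- paste0("s", 1:12)
  cl <- hcluster(blob, "euclidean", "ward")
  labels <- cut_clusters(cl, 2)
  expect_equal(length(unique(labels[1:6])), 1L)
  expect_equal(length(unique(labels[7:12])), 1L)
  expect_false(labels[1] == labels[7])
  # exact duplicates merge at height zero
  dup <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 4))
  expect_equal(min(hcluster(dup, "euclidean", "ward")$tree$height), 0)
  # zero-variance column dropped under Pearson with a warning
  zv <- cbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(3, 1, 2))
  expect_warning(hcluster(zv, "one_minus_pearson", "average"), "b")
  expect_error(hcluster(dup[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("signature derivation recovers the planted set with pure clusters", {
  cfg <- simulation_config(seed = 8, noise_sd_log2 = 0.25,
                           class_effect_fold = 1)
  cl <- generate_clinical_cohorts(cfg)
  sig <- derive_signature(cl$A$matrix, nepc_ad_labels(cl$A$metadata),
                          cl$B$matrix, nepc_ad_labels(cl$B$metadata))
  truth <- cl$truth$transcript_key[grepl("signature",
                                         cl$truth$planted_role)]
  jac <- length(intersect(sig$signature, truth)) /
    length(union(sig$signature, truth))
  expect_gte(jac, 0.9)
  expect_equal(unname(sig$purity), c(1, 1))
  # per-cohort lists respect the percentile size
  expect_lte(length(sig$perA), ceiling(0.05 * cfg$n_transcripts))
})

test_that("uncharacterized names are excluded from the signature", {
  cfg <- simulation_config(seed = 18, n_transcripts = 200L,
                           n_planted_per_class = 2L, signature_size = 10L,
                           class_effect_fold = 1)
  cl <- generate_clinical_cohorts(cfg)
  truth <- cl$truth$transcript_key[grepl("signature",
                                         cl$truth$planted_role)]
  gene_names <- setNames(rownames(cl$A$matrix), rownames(cl$A$matrix))
  gene_names[truth[1:3]] <- c("RP11-10A1.2", "AC000001.1", "AL000002.9")
  sig <- derive_signature(cl$A$matrix, nepc_ad_labels(cl$A$metadata),
                          cl$B$matrix, nepc_ad_labels(cl$B$metadata),
                          gene_names = gene_names)
  expect_false(any(truth[1:3] %in% sig$signature))
  expect_true(all(truth[4:10] %in% sig$signature))
})

test_that("disjoint top-variance sets give an empty signature", {
  set.seed(45)
  base <- matrix(2 * 2^rnorm(40 * 12, 0, 0.05), 40, 12,
                 dimnames = list(sprintf("t%02d", 1:40),
                                 paste0("s", 1:12)))
  a <- base; a[1:2, 1:6] <- a[1:2, 1:6] * 50
  b <- base; b[39:40, 1:6] <- b[39:40, 1:6] * 50
  labels <- setNames(rep(c("NEPC", "AD"), each = 6), paste0("s", 1:12))
  expect_warning(
    sig <- derive_signature(a, labels, b, labels),
    "empty signature")
  expect_length(sig$signature, 0L)
})

test_that("signature ranking applies concordance and magnitude rules", {
  sigkeys <- c("both_up", "weak_b", "discordant", "both_down")
  mk <- function(nepc_fold) {
    m <- matrix(10, 4, 8, dimnames = list(sigkeys, paste0("s", 1:8)))
    m[, 5:8] <- m[, 5:8] * nepc_fold
    m
  }
  md <- data.frame(sample_id = paste0("s", 1:8),
                   phenotype_group = rep(c("AD", "NEPC"), each = 4),
                   stringsAsFactors = FALSE)
  a <- mk(c(30, 15, 12, 1 / 30))
  b <- mk(c(30, 1.2, 1 / 12, 1 / 30))
  rk <- rank_signature(a, md, b, md, sigkeys, pseudocount = 0)
  flagged <- rk$transcript_key[rk$flagged]
  expect_setequal(flagged, c("both_up", "both_down"))
  expect_false(rk$concordant[rk$transcript_key == "discordant"])
  expect_error(rank_signature(a, md, b, md, character()), "empty")
})

test_that("pca_top3 identifies low-dimensional structure", {
  # samples on a line: one component explains ~everything
  line <- rbind(seq(1, 10), 2 * seq(1, 10), -seq(1, 10))
  colnames(line) <- paste0("s", 1:10)
  p <- pca_top3(line)
  expect_gt(p$variance_fraction[1], 0.999)
  expect_equal(ncol(p$scores), 3L)
  expect_lte(sum(p$variance_fraction), 1 + 1e-12)
  # fewer than three samples: as many components as possible
  two <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_lte(ncol(pca_top3(two)$scores), 2L)
})
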
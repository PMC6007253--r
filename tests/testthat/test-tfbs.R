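test_that("continuity-corrected z-score follows the formula exactly", {
  expect_equal(enrichment_z(10, 4.5, 2), 2.5)
  expect_equal(enrichment_z(0, 9.5, 3), -10 / 3)
  expect_equal(enrichment_z(7.5, 7, 4), 0)   # x = E + 0.5
  expect_error(enrichment_z(5, 2, 0), "> 0")
  # strictly increasing in x, decreasing in E
  expect_true(all(diff(enrichment_z(1:20, 5, 2)) > 0))
  expect_true(all(diff(enrichment_z(10, seq(1, 9, 0.5), 2)) < 0))
})

test_that("z to two-sided p matches the normal tail", {
  expect_equal(z_to_p(2), 0.04550026, tolerance = 1e-7)
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(z_to_p(-2), z_to_p(2))
})

test_that("binomial background expectation handles degenerate rates", {
  be <- background_expectation(100, 0.05)
  expect_equal(be$E, 5)
  expect_equal(be$S, sqrt(4.75))
  expect_true(be$scorable)
  expect_false(background_expectation(100, 0)$scorable)
  expect_false(background_expectation(100, 1)$scorable)
  expect_error(background_expectation(10, 1.5), "\\[0, 1\\]")
})

test_that("consensus scanning counts overlaps and both strands", {
  expect_equal(scan_consensus("AACGTT", "ACGT", both_strands = FALSE), 1L)
  expect_equal(scan_consensus("AAGTACGT", "ANGT", both_strands = FALSE), 2L)
  # palindromic motif doubles when both strands are scanned
  expect_equal(scan_consensus("ACGTACGT", "ACGT", both_strands = TRUE), 4L)
  expect_equal(scan_consensus("ACGTACGT", "ACGT", both_strands = FALSE), 2L)
  # overlapping matches all count
  expect_equal(scan_consensus("AAAAA", "AAAA", both_strands = FALSE), 2L)
  expect_error(scan_consensus("ACGT", "ACXT"), "invalid IUPAC")
  expect_error(scan_consensus("ACGTACGT", "ACG"), ">= 4")
})

test_that("scanner agrees with a position-by-position oracle", {
  set.seed(51)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")
  for (i in 1:500) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1),
                        replace = TRUE), collapse = "")
    motif <- paste(sample(codes, sample(4:8, 1), replace = TRUE,
                          prob = c(rep(4, 4), rep(1, 7))),
                   collapse = "")
    both <- runif(1) < 0.5
    expect_equal(scan_consensus(seq, motif, both),
                 oracle_scan(seq, motif, both))
  }
})

test_that("class enrichment flags planted over-representation", {
  cfg <- simulation_config(seed = 14, n_promoters_per_class = 30L,
                           promoter_length = 400L)
  motifs <- c(planted = "TGACGTCA", background = "CCCGWTAA")
  rates <- list(I_Deactivated = c(planted = 0.9), II_Activated = 0,
                III_Persistent = 0, IV_Transient = 0)
  prom <- generate_promoters_and_hits(cfg, motifs, insert_rate = rates)
  # background rate estimated from the scan geometry of random sequence
  p_bg <- vapply(motifs, function(m) {
    w <- nchar(m)
    n_deg <- prod(vapply(strsplit(m, "")[[1]],
                         function(l) length(IUPAC_SETS[[l]]), 0))
    n_deg / 4^w
  }, 0)
  background <- data.frame(motif_id = names(motifs), p = unname(p_bg),
                           stringsAsFactors = FALSE)
  enr <- class_enrichment(prom$hits, background)
  planted_row <- enr[enr$class_label == "I_Deactivated" &
                       enr$motif_id == "planted", ]
  expect_true(planted_row$significant)
  expect_gt(planted_row$z, 2)
  null_rows <- enr[enr$motif_id == "background", ]
  expect_true(all(abs(null_rows$z) < 4))
  # explicit (E, S) backgrounds are used verbatim
  es <- data.frame(motif_id = "planted", E = 4.5, S = 2,
                   stringsAsFactors = FALSE)
  one <- data.frame(class_label = "I_Deactivated", motif_id = "planted",
                    x = 10, stringsAsFactors = FALSE)
  expect_equal(class_enrichment(one, es)$z, 2.5)
  # missing background is skipped with a warning
  expect_warning(out <- class_enrichment(one, data.frame(
    motif_id = "other", E = 1, S = 1)), "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("insertion rate zero leaves hit counts at background scan counts", {
  cfg <- simulation_config(seed = 15, n_promoters_per_class = 10L,
                           promoter_length = 300L)
  motifs <- c(m1 = "ACGTACGT")
  prom <- generate_promoters_and_hits(cfg, motifs)
  manual <- sum(scan_consensus(prom$sequences$I_Deactivated, "ACGTACGT"))
  row <- prom$hits[prom$hits$class_label == "I_Deactivated", ]
  expect_equal(row$x, manual)
  # rate 1: at least one hit per sequence
  prom1 <- generate_promoters_and_hits(
    cfg, motifs, insert_rate = c(I_Deactivated = 1))
  counts <- scan_consensus(prom1$sequences$I_Deactivated, "ACGTACGT")
  expect_true(all(counts >= 1))
  expect_error(generate_promoters_and_hits(cfg, character()), "non-empty")
  expect_error(generate_promoters_and_hits(cfg, c(bad = "ACQT")),
               "invalid IUPAC")
})

test_that("unique/common motif logic follows the significance pattern", {
  res <- expand.grid(class_label = paste0("C", 1:4),
                     motif_id = c("only1", "all", "two", "none"),
                     stringsAsFactors = FALSE)
  res$significant <- with(res,
    (motif_id == "only1" & class_label == "C1") |
    motif_id == "all" |
    (motif_id == "two" & class_label %in% c("C1", "C2")))
  uc <- unique_and_common(res)
  expect_equal(uc$unique_per_class$C1, "only1")
  expect_equal(uc$common, "all")
  expect_false("two" %in% unlist(uc$unique_per_class))
  expect_false("two" %in% uc$common)
  expect_error(unique_and_common(res[res$class_label == "C1", ]),
               ">= 2 classes")
})

test_that("presence distributions recover the planted split", {
  classes <- list(I = paste0("a", 1:6), II = paste0("b", 1:2),
                  III = "c1", IV = "d1")
  tx <- unlist(classes)
  presence <- matrix(FALSE, length(tx), 3,
                     dimnames = list(tx, c("m_split", "m_only4",
                                           "m_absent")))
  presence[c(paste0("a", 1:6), paste0("b", 1:2), "c1", "d1"),
           "m_split"] <- TRUE
  presence["d1", "m_only4"] <- TRUE
  dist <- tfbs_distribution(classes, presence)
  expect_equal(unname(dist["m_split", ]), c(0.6, 0.2, 0.1, 0.1))
  expect_equal(unname(dist["m_only4", ]), c(0, 0, 0, 1))
  expect_false("m_absent" %in% rownames(dist))
  expect_equal(unname(rowSums(dist)), rep(1, nrow(dist)))
})
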
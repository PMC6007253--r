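test_that("class ranking keys follow the per-class rules", {
  netd_sets <- list(I_Deactivated = c("d1", "d2"),
                    II_Activated = character(0),
                    III_Persistent = c("p1", "p2"),
                    IV_Transient = c("t1", "t2"))
  mk <- function(label, keys, fc) data.frame(
    transcript_key = keys, comparison = label, fold_change = fc,
    stringsAsFactors = FALSE)
  keys <- c("d1", "d2", "p1", "p2", "t1", "t2")
  results_a <- rbind(
    mk("NEPC_vs_AD", keys, c(0.1, 0.4, 6, 2, 1, 1)),
    mk("CRPC_vs_AD", keys, c(0.2, 0.3, 1, 1, 1, 1)),
    mk("NHT_vs_NAIVE", keys, c(0.3, 0.2, 1, 1, 3, 1 / 8)),
    mk("NEPC_vs_NHT", keys, c(1, 1, 1, 1, 1 / 2, 1 / 3)))
  results_b <- mk("NEPC_vs_AD", keys, c(0.5, 0.5, 4, 9, 1, 1))
  sig_rank <- data.frame(
    transcript_key = c("s_up", "s_dn"), fc_a = c(30, 1 / 25),
    fc_b = c(20, 1 / 30), concordant = TRUE, flagged = TRUE,
    stringsAsFactors = FALSE)
  rk <- rank_class_transcripts(netd_sets, results_a, results_b, sig_rank,
                               top_n = 2)
  # Class I: min fold across the three contrasts, strongest decline first
  expect_equal(rk$per_class$I_Deactivated$transcript_key, c("d1", "d2"))
  expect_equal(rk$per_class$I_Deactivated$rank_key, c(0.1, 0.2))
  # Class III: max NEPC-vs-AD fold across cohorts, descending magnitude
  expect_equal(rk$per_class$III_Persistent$transcript_key, c("p2", "p1"))
  expect_equal(rk$per_class$III_Persistent$rank_key, c(9, 6))
  # Class IV: max |fold| of the two transition contrasts
  expect_equal(rk$per_class$IV_Transient$transcript_key, c("t2", "t1"))
  expect_equal(rk$per_class$IV_Transient$rank_key, c(8, 3))
  # groups (one class empty here) and duplicates collapsed
  expect_setequal(unique(rk$selected$group),
                  c("I_Deactivated", "III_Persistent", "IV_Transient",
                    "signature"))
  expect_setequal(
    rk$selected$transcript_key[rk$selected$group == "signature"],
    c("s_up", "s_dn"))
  expect_equal(length(rk$unique_keys), nrow(rk$selected))
  expect_error(
    rank_class_transcripts(netd_sets, results_a[
      results_a$comparison != "CRPC_vs_AD", ], results_b, sig_rank),
    "CRPC_vs_AD")
})

test_that("full-size ranking yields five groups of twenty", {
  keys <- sprintf("k%03d", 1:200)
  netd_sets <- split(keys[1:120], rep(c("I_Deactivated", "II_Activated",
                                        "III_Persistent", "IV_Transient"),
                                      each = 30))
  set.seed(61)
  mk <- function(label) data.frame(
    transcript_key = keys, comparison = label,
    fold_change = 2^rnorm(200), stringsAsFactors = FALSE)
  results_a <- rbind(mk("NEPC_vs_AD"), mk("CRPC_vs_AD"),
                     mk("NHT_vs_NAIVE"), mk("NEPC_vs_NHT"))
  sig_rank <- data.frame(
    transcript_key = keys[121:200], fc_a = 2^rnorm(80, 0, 3),
    stringsAsFactors = FALSE)
  sig_rank$fc_b <- sig_rank$fc_a
  sig_rank$concordant <- TRUE
  sig_rank$flagged <- FALSE
  rk <- rank_class_transcripts(netd_sets, results_a, mk("NEPC_vs_AD"),
                               sig_rank)
  expect_equal(nrow(rk$selected), 100L)
  expect_equal(as.vector(table(rk$selected$group)), rep(20L, 5))
  expect_equal(length(unique(rk$selected$group)), 5L)
})

test_that("probes map only when fully contained in an exon", {
  exons <- data.frame(
    transcript_id = c("tx1", "tx1", "tx2"), chrom = "chr1",
    start = c(100L, 300L, 1000L), end = c(200L, 400L, 1200L),
    stringsAsFactors = FALSE)
  probes <- data.frame(
    probe_id = c("inside", "straddle", "intergenic", "exact"),
    chrom = "chr1",
    start = c(150L, 190L, 500L, 300L),
    end = c(170L, 210L, 520L, 400L),
    stringsAsFactors = FALSE)
  mp <- map_probes(probes, exons)
  expect_setequal(mp$mapping$probe_id, c("inside", "exact"))
  expect_equal(mp$measurable_transcripts, "tx1")
  expect_equal(mp$mapped_fraction, 0.5)
  # invariant to exon list order
  mp2 <- map_probes(probes, exons[c(3, 1, 2), ])
  expect_equal(mp2$mapped_fraction, mp$mapped_fraction)
  expect_equal(map_probes(probes[0, ], exons)$mapped_fraction, 0)
  expect_error(map_probes(data.frame(probe_id = "x", chrom = "chr1",
                                     start = 10L, end = 10L), exons),
               "malformed")
})

test_that("generated probe maps recover the containment fraction", {
  cfg <- simulation_config(seed = 16)
  models <- generate_transcript_models(cfg, n = 122L)
  pm <- generate_probe_map(cfg, models)
  mp <- map_probes(pm$probes, models$exons)
  # liftover decisions match the planted truth exactly
  mapped <- pm$truth$probe_id %in% mp$mapping$probe_id
  expect_equal(mapped, pm$truth$contained)
  # binomial band around 0.87 * 122 = 106
  expect_lt(abs(sum(mapped) - 106), 3 * sqrt(122 * 0.87 * 0.13) + 1)
  # extremes
  all_in <- generate_probe_map(
    simulation_config(seed = 16, containment_frac = 1), models)
  expect_true(all(all_in$truth$contained))
  none_in <- generate_probe_map(
    simulation_config(seed = 16, containment_frac = 0), models)
  expect_false(any(none_in$truth$contained))
})

test_that("AUC matches exhaustive pair counting and spec examples", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(c(5, 5, 5, 5), c(0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both label")
  set.seed(62)
  for (i in 1:200) {
    n <- sample(6:25, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  # complement identity on tie-free inputs
  for (i in 1:20) {
    scores <- sample(seq(0.01, 1, 0.01), 15)
    labels <- c(TRUE, FALSE, runif(13) < 0.5)
    expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
  }
  # independent cross-check against pROC
  set.seed(63)
  scores <- rnorm(40)
  labels <- c(TRUE, FALSE, runif(38) < 0.5)
  expect_equal(
    roc_auc(scores, labels),
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   direction = "<"))))
})

test_that("rapid-metastasis labels follow the clinical windows", {
  md <- data.frame(
    adt_treated = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    metastasis_event = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    time_to_metastasis_months = c(24, NA, NA, 24, 60),
    followup_months = c(24, 130, 60, 24, 60))
  lab <- define_rapid_met_groups(md)
  expect_equal(lab, c(TRUE, FALSE, NA, NA, NA))
})

test_that("median-split Kaplan-Meier matches a hand-worked log-rank table", {
  md <- data.frame(
    sample_id = paste0("s", 1:4), adt_treated = TRUE,
    time_to_metastasis_months = 1:4, metastasis_event = TRUE,
    followup_months = 1:4, stringsAsFactors = FALSE)
  expr <- setNames(c(1, 2, 10, 11), md$sample_id)
  km <- km_median_split(expr, md, "treated")
  # hand table: O_high = 2, E_high = 0.5 + 2/3 + 1 + 1, V = 1/4 + 2/9
  expect_equal(km$chisq, (2 - (0.5 + 2 / 3 + 1 + 1))^2 / (1 / 4 + 2 / 9),
               tolerance = 1e-10)
  expect_equal(km$logrank_p, 0.08955507, tolerance = 1e-7)
  # ties at the median go to the low group
  md5 <- data.frame(
    sample_id = paste0("s", 1:5), adt_treated = TRUE,
    time_to_metastasis_months = 1:5, metastasis_event = TRUE,
    followup_months = 1:5, stringsAsFactors = FALSE)
  expr_tie <- setNames(c(1, 2, 2, 9, 10), md5$sample_id)
  km_tie <- km_median_split(expr_tie, md5, "treated")
  expect_equal(unname(table(km_tie$groups)["low"]), 3L)
  # no censoring: KM equals the empirical survival function
  s <- summary(km$fit)
  low_surv <- s$surv[s$strata == "group=low"]
  expect_equal(low_surv, c(0.5, 0))
  # identical event-time groups are null
  md2 <- md; md2$time_to_metastasis_months <- c(2, 3, 2, 3)
  md2$followup_months <- c(2, 3, 2, 3)
  km2 <- km_median_split(setNames(c(1, 1, 8, 8), md$sample_id), md2,
                         "treated")
  expect_gt(km2$logrank_p, 0.9)
})

test_that("delta-delta-Ct arithmetic reproduces worked examples", {
  ct <- data.frame(
    target = rep(c("LNC1", "PSMB4"), each = 6),
    sample = rep(rep(c("case", "ref"), each = 3), 2),
    ct = c(rep(20, 3), rep(24, 3), rep(18, 6)),
    stringsAsFactors = FALSE)
  out <- ddct_fold_change(ct, "PSMB4", "ref")
  case <- out[out$sample == "case", ]
  # dCt 2 vs 6 -> ddCt = -4 -> fold 16
  expect_equal(case$delta_delta_ct, -4)
  expect_equal(case$fold_change, 16)
  ref <- out[out$sample == "ref", ]
  expect_equal(ref$fold_change, 1)
  # triplicate spread is reported
  ct2 <- ct; ct2$ct[1:3] <- c(19, 20, 21)
  out2 <- ddct_fold_change(ct2, "PSMB4", "ref")
  expect_equal(out2$ct_sd[out2$sample == "case"], 1)
  expect_error(ddct_fold_change(ct, "GAPDH", "ref"), "housekeeper")
})

test_that("planted outcome cohorts separate only in the treated arm", {
  aucs_t <- aucs_u <- numeric(0)
  for (s in 1:20) {
    cfg <- simulation_config(seed = s, outcome_hazard_fold = 6)
    oc <- generate_outcome_cohort(cfg)
    x <- oc$matrix["OTX_PRED01", ]
    md <- oc$metadata
    lab <- define_rapid_met_groups(md)
    keep <- !is.na(lab)
    aucs_t <- c(aucs_t, roc_auc(x[keep], lab[keep]))
    # same windows computed in the untreated arm, ignoring treatment
    labu <- rep(NA, nrow(md))
    un <- !md$adt_treated
    labu[un & md$metastasis_event &
           md$time_to_metastasis_months < 36] <- TRUE
    labu[un & !md$metastasis_event & md$followup_months >= 120] <- FALSE
    keepu <- !is.na(labu)
    aucs_u <- c(aucs_u, roc_auc(x[keepu], labu[keepu]))
  }
  expect_gt(mean(aucs_t), 0.8)
  expect_gt(mean(aucs_u), 0.4)
  expect_lt(mean(aucs_u), 0.6)
})
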
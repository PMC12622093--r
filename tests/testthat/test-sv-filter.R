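test_that("truth-set labeling applies the distance and size-similarity predicate", {
  truth <- data.frame(chrom = "chr1", pos = c(1000L, 50000L),
                      svtype = c("DEL", "INS"), svlen = c(-300L, 400L))
  cand <- data.frame(chrom = "chr1", pos = c(1010L, 60000L),
                     svtype = c("DEL", "INS"), svlen = c(-310L, 400L))
  lab <- label_calls(cand, truth)
  expect_equal(lab$label, c("TP", "FP"))  # second is 10 kbp away

  # size similarity below 0.7 blocks a positional match
  cand2 <- data.frame(chrom = "chr1", pos = 1000L, svtype = "DEL", svlen = -100L)
  expect_equal(label_calls(cand2, truth)$label, "FP")

  expect_error(label_calls(cand[2:1, ], truth), "sorted")

  # greedy matching consumes each truth record at most once and agrees with
  # an optimal assignment in nearly all calls on randomized sets
  withr::with_seed(61, {
    for (rep in 1:5) {
      tr <- data.frame(chrom = "chr1",
                       pos = sort(sample.int(1e6, 100)),
                       svtype = sample(c("INS", "DEL"), 100, TRUE),
                       svlen = sample(c(-500:-50, 50:500), 100, TRUE))
      cd <- tr
      cd$pos <- cd$pos + sample(-400:400, 100, TRUE)
      cd <- cd[order(cd$chrom, cd$pos), ]
      lab <- label_calls(cd, tr)
      expect_false(anyDuplicated(lab$matched_truth[!is.na(lab$matched_truth)]) > 0)
      # brute-force maximum bipartite matching under the same predicate
      edges <- list()
      for (i in seq_len(nrow(cd))) for (j in seq_len(nrow(tr))) {
        if (cd$svtype[i] == tr$svtype[j] &&
            abs(cd$pos[i] - tr$pos[j]) <= 500 &&
            min(abs(cd$svlen[i]), abs(tr$svlen[j])) /
              max(abs(cd$svlen[i]), abs(tr$svlen[j])) >= 0.7) {
          edges[[length(edges) + 1L]] <- c(i, j)
        }
      }
      em <- do.call(rbind, edges)
      # greedy maximal matching size vs augmenting-path optimal
      match_t <- rep(NA_integer_, nrow(tr))
      try_kuhn <- function(i, seen) {
        for (j in em[em[, 1] == i, 2]) {
          if (!seen[j]) {
            seen[j] <- TRUE
            if (is.na(match_t[j]) || try_kuhn(match_t[j], seen)) {
              match_t[j] <<- i
              return(TRUE)
            }
          }
        }
        FALSE
      }
      for (i in unique(em[, 1])) try_kuhn(i, logical(nrow(tr)))
      optimal <- sum(!is.na(match_t))
      greedy <- sum(lab$label == "TP")
      expect_gte(greedy / optimal, 0.99)
    }
  })
})

test_that("filter training is seeded-deterministic with calibrated null and strong-signal AUC", {
  tab <- gen_sv_feature_table(sv_sim_spec(n_calls = 2000, seed = 8))
  m1 <- train_filter(tab, seed = 8)
  m2 <- train_filter(tab, seed = 8)
  expect_identical(score_calls(m1, tab), score_calls(m2, tab))

  expect_error(train_filter(tab[tab$label == "TP", ], seed = 1), "both classes")
  expect_error(train_filter(tab[1:50, ], seed = 1), "100")

  # strong signal: held-out AUC > 0.95 by the rank statistic
  big <- gen_sv_feature_table(sv_sim_spec(n_calls = 6000,
                                          effect_sizes = rep(3, 4), seed = 9))
  train <- big[1:3000, ]; test <- big[3001:6000, ]
  m <- train_filter(train, seed = 9)
  expect_gt(rank_auc(score_calls(m, test), test$label), 0.95)

  # no-signal null: held-out AUC ~ 0.5
  null <- gen_sv_feature_table(sv_sim_spec(n_calls = 6000,
                                           effect_sizes = rep(0, 4), seed = 10))
  mn <- train_filter(null[1:3000, ], seed = 10)
  auc0 <- rank_auc(score_calls(mn, null[3001:6000, ]), null$label[3001:6000])
  expect_lt(abs(auc0 - 0.5), 0.03)
})

test_that("threshold selection hits the target and matches the exhaustive sweep oracle", {
  # perfectly separated scores
  sep <- select_threshold(c(rep(1, 50), rep(0, 50)),
                          rep(c("TP", "FP"), each = 50), 0.9)
  expect_equal(sep$achieved_tpr, 1)
  expect_equal(sep$achieved_fpr, 0)
  expect_error(select_threshold(1, "TP", 1.5), "target")

  tab <- gen_sv_feature_table(sv_sim_spec(n_calls = 10000, seed = 12))
  m <- train_filter(tab, seed = 12)
  s <- score_calls(m, tab)
  for (target in c(0.9, 0.7)) {
    sel <- select_threshold(s, tab$label, target)
    expect_lt(abs(sel$achieved_tpr - target), 0.02)
    expect_equal(sel$threshold, oracle_threshold(s, tab$label, target))
  }
})

test_that("strict output is nested in lenient output and thresholds are coherent", {
  tab <- gen_sv_feature_table(sv_sim_spec(n_calls = 2000, seed = 13))
  m <- threshold_filter(train_filter(tab, seed = 13), tab)
  expect_gte(m$thresholds$strict$threshold, m$thresholds$lenient$threshold)
  expect_gte(m$thresholds$lenient$achieved_tpr, m$thresholds$strict$achieved_tpr)
  len <- apply_filter(tab, m, "lenient")
  st <- apply_filter(tab, m, "strict")
  expect_true(all(st$call_id %in% len$call_id))

  # degenerate thresholds
  m$thresholds$lenient$threshold <- 0
  expect_equal(nrow(apply_filter(tab, m, "lenient")), nrow(tab))
  m$thresholds$strict$threshold <- 1 + 1e-9
  expect_equal(nrow(apply_filter(tab, m, "strict")), 0L)
})

test_that("null calibration: without signal the TPR-0.9 cut keeps ~90% of both classes", {
  null <- gen_sv_feature_table(sv_sim_spec(n_calls = 10000,
                                           effect_sizes = rep(0, 4), seed = 14))
  held <- null[5001:10000, ]
  # train on one half, pick the operating point on the held-out half so the
  # threshold reflects the score scale on unseen data
  m <- threshold_filter(train_filter(null[1:5000, ], seed = 14), held)
  s <- score_calls(m, held)
  keep <- s >= m$thresholds$lenient$threshold
  # on held-out data the filter can claim no specificity without signal
  expect_lt(abs(mean(keep[held$label == "TP"]) - 0.9), 0.06)
  expect_lt(abs(mean(keep[held$label == "FP"]) - 0.9), 0.06)
})

test_that("Mendelian classification matches the 27-triplet transmission enumeration", {
  expect_false(mendelian_consistent("0/0", "0/0", "0/1"))
  for (g in c("0/0", "0/1", "1/1")) {
    expect_true(mendelian_consistent("0/1", "0/1", g))
  }
  gts <- c("0/0", "0/1", "1/1")
  for (f in gts) for (m in gts) for (c in gts) {
    expect_equal(mendelian_consistent(f, m, c), oracle_mendel(f, m, c),
                 label = paste(f, m, c))
  }
  expect_true(is.na(mendelian_consistent("./.", "0/0", "0/0")))

  tr <- data.frame(father = c("0/0", "0/0", "./."),
                   mother = c("0/0", "0/1", "0/0"),
                   child = c("0/1", "0/1", "0/0"))
  md <- mendelian_discordance(tr)
  expect_equal(md$n_complete, 2L)
  expect_equal(md$rate, 0.5)
  md2 <- mendelian_discordance(tr, missing_as_discordant = TRUE)
  expect_equal(md2$rate, 2 / 3)
  expect_error(mendelian_discordance(data.frame(father = "./.", mother = "./.",
                                                child = "./.")),
               "undefined")
})

test_that("exact HWE test agrees with full enumeration probabilities", {
  # tiny case checkable by hand: n=2, one het observed
  # allele count n_a = 1 -> only h=1 possible -> p = 1
  expect_equal(hwe_exact_test(1, 1, 0), 1)
  # het excess is detected
  expect_lt(hwe_exact_test(0, 200, 0), 1e-10)
  # enumeration cross-check: probabilities over het configurations sum to 1
  # and the two-sided p equals the mass of configurations no more likely
  n_AA <- 21; n_Aa <- 18; n_aa <- 11
  n <- 50; n_a <- 2 * n_aa + n_Aa
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  probs <- sapply(hets, function(h) {
    aa <- (n_a - h) / 2; AA <- n - aa - h
    exp(lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
        h * log(2) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1))
  })
  expect_equal(sum(probs), 1, tolerance = 1e-10)
  p_manual <- sum(probs[probs <= probs[hets == n_Aa] + 1e-12])
  expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa), p_manual, tolerance = 1e-10)
})

test_that("panel postfilters remove exactly the rule-violating records in order", {
  v <- data.frame(
    variant_id = sprintf("v%02d", 1:8),
    chrom = "chr1",
    pos = c(100L, 5000L, 5000L, 9000L, 40000L, 70000L, 90000L, 90000L),
    type = c("SNV", "SV", "SNV", "SNV", "SNV", "SNV", "SNV", "SNV"),
    allele_count = c(1L, 10L, 10L, 20L, 8L, 8L, 10L, 12L),
    af = c(0.001, 0.1, 0.05, 0.2, 0.004, 0.004, 0.01, 0.02))
  res <- panel_postfilter(v)
  log <- res$removal_log
  expect_equal(log$variant_id[log$rule == 1], "v01")           # singleton
  expect_equal(log$variant_id[log$rule == 2], "v03")           # SV duplicate
  # v05 is rare but 35 kbp from the SV at 5000 -> removed by rule 3;
  # v06 rare at 65 kbp -> also removed; make one close instead:
  expect_true(all(c("v05", "v06") %in% log$variant_id[log$rule == 3]))
  expect_equal(log$variant_id[log$rule == 4], "v07")           # lower AF at 90000
  expect_setequal(res$retained$variant_id, c("v02", "v04", "v08"))

  # rule-3 conjunction: rare but close to an SV is retained
  v2 <- data.frame(variant_id = c("sv", "near"), chrom = "chr1",
                   pos = c(5000L, 15000L), type = c("SV", "SNV"),
                   allele_count = c(10L, 5L), af = c(0.1, 0.004))
  expect_true("near" %in% panel_postfilter(v2)$retained$variant_id)
})

test_that("cohort QC boundary values pass exactly as printed", {
  # all metrics exactly at their passing boundaries are retained
  tab <- data.frame(variant_id = "v1", mean_gp = 0.7,
                    af_panel = 0.10, af_imputed = 0.10,
                    carrier_concordance = 0.70, n_carriers = 10L,
                    hwe_p = 1e-5)
  expect_equal(apply_phewas_qc(tab)$retained, "v1")
  # each removal inequality as printed
  expect_equal(length(apply_phewas_qc(transform(tab, mean_gp = 0.69))$retained), 0L)
  expect_equal(length(apply_phewas_qc(transform(tab, hwe_p = 0.9e-5))$retained), 0L)
  expect_equal(length(apply_phewas_qc(transform(tab, af_imputed = 0.16))$retained), 0L)
  expect_equal(length(apply_phewas_qc(transform(tab, carrier_concordance = 0.699))$retained), 0L)
  expect_equal(length(apply_phewas_qc(transform(tab, n_carriers = 9L))$retained), 0L)
  # AF of zero in one cohort only -> infinite fold change -> removed
  z <- apply_phewas_qc(transform(tab, af_imputed = 0))
  expect_equal(length(z$retained), 0L)
  expect_equal(unname(z$rule_counts["af"]), 1L)
  # fold change exactly 1.5 is removed (">= 1.5-fold" is the removal rule)
  expect_equal(length(apply_phewas_qc(transform(tab, af_imputed = 0.15))$retained), 0L)
  expect_equal(length(apply_phewas_qc(transform(tab, af_imputed = 0.149))$retained), 1L)
})
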
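#' Label candidate SV calls against a truth set
#'
#' A candidate is a true positive iff some truth record of the same type on
#' the same chromosome lies within `max_dist` bp and the two lengths agree to
#' a size similarity `min(|a|,|b|)/max(|a|,|b|) >= min_size_sim`. Matching is
#' greedy nearest-first with each truth record consumed at most once.
#'
#' @param candidates,truth Data frames with columns `chrom`, `pos`, `svtype`,
#'   `svlen`, sorted by (chrom, pos).
#' @param max_dist Maximum start distance in bp (default 500).
#' @param min_size_sim Minimum size similarity (default 0.7).
#' @return `candidates` with an added `label` column in {"TP", "FP"} and a
#'   `matched_truth` index column (NA for FP).
#' @export
label_calls <- function(candidates, truth, max_dist = 500, min_size_sim = 0.7) {
  for (d in list(candidates, truth)) {
    o <- order(d$chrom, d$pos)
    if (!identical(o, seq_len(nrow(d)))) stop("input must be sorted by (chrom, pos)")
  }
  label <- rep("FP", nrow(candidates))
  matched <- rep(NA_integer_, nrow(candidates))
  pairs <- list()
  for (i in seq_len(nrow(candidates))) {
    j <- which(truth$chrom == candidates$chrom[i] &
               truth$svtype == candidates$svtype[i] &
               abs(truth$pos - candidates$pos[i]) <= max_dist)
    if (length(j)) {
      ssim <- pmin(abs(truth$svlen[j]), abs(candidates$svlen[i])) /
        pmax(abs(truth$svlen[j]), abs(candidates$svlen[i]))
      j <- j[ssim >= min_size_sim]
      for (jj in j) {
        pairs[[length(pairs) + 1L]] <- c(i, jj, abs(truth$pos[jj] - candidates$pos[i]))
      }
    }
  }
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 3]), , drop = FALSE]
    used_c <- logical(nrow(candidates)); used_t <- logical(nrow(truth))
    for (k in seq_len(nrow(pm))) {
      i <- pm[k, 1]; j <- pm[k, 2]
      if (!used_c[i] && !used_t[j]) {
        used_c[i] <- TRUE; used_t[j] <- TRUE
        label[i] <- "TP"; matched[i] <- j
      }
    }
  }
  out <- candidates
  out$label <- label
  out$matched_truth <- matched
  out
}

SV_FEATURES <- c("allele_depth", "allele_balance", "length", "caller_support")

#' Train the SV-call filter model
#'
#' Fits a gradient-boosted tree classifier (the package's pinned scorer
#' family) on the four genotyping features: allele depth, allele balance,
#' variant length, and multi-caller support. Deterministic given the seed
#' (single-threaded training). The returned model is unthresholded; attach
#' operating points with [select_threshold()].
#'
#' @param labeled Data frame with the four feature columns and a `label`
#'   column in {"TP", "FP"}; both classes present, n >= 100.
#' @param seed Integer training seed, recorded in the model metadata.
#' @param nrounds,max_depth,eta Boosting hyperparameters (fixed defaults).
#' @return Object of class `filter_model`: `booster`, `features`, `seed`,
#'   `thresholds` (empty until selected), `metadata`.
#' @export
train_filter <- function(labeled, seed = 1L, nrounds = 50L, max_depth = 3L,
                         eta = 0.3) {
  stopifnot(all(SV_FEATURES %in% names(labeled)), "label" %in% names(labeled))
  y <- as.integer(labeled$label == "TP")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (nrow(labeled) < 100) stop("need at least 100 labeled calls")
  x <- as.matrix(labeled[, SV_FEATURES])
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
  booster <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1L, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0))
  structure(list(booster = booster, features = SV_FEATURES, seed = seed,
                 thresholds = list(),
                 metadata = list(scorer = "xgboost/binary:logistic",
                                 nrounds = nrounds, max_depth = max_depth,
                                 eta = eta)),
            class = "filter_model")
}

#' Score records with a trained filter model
#'
#' @param model A `filter_model`.
#' @param records Data frame carrying the four feature columns.
#' @return Numeric vector of probability-like scores in (0, 1).
#' @export
score_calls <- function(model, records) {
  stopifnot(inherits(model, "filter_model"))
  predict(model$booster,
          xgboost::xgb.DMatrix(as.matrix(records[, model$features]),
                               nthread = 1L))
}

#' Select a score threshold targeting a true positive rate
#'
#' Chooses the largest score cut whose TPR on the supplied labels still meets
#' the target — the most specific operating point meeting the target — and
#' reports the achieved TPR/FPR at that cut.
#'
#' @param scores Numeric score vector.
#' @param labels Character vector in {"TP", "FP"} (>= 1 TP).
#' @param target_tpr Target true positive rate in (0, 1].
#' @return List: `threshold`, `achieved_tpr`, `achieved_fpr`, `target_tpr`.
#' @export
select_threshold <- function(scores, labels, target_tpr) {
  if (target_tpr > 1 || target_tpr <= 0) stop("target TPR must be in (0, 1]")
  tp_scores <- scores[labels == "TP"]
  fp_scores <- scores[labels == "FP"]
  if (length(tp_scores) == 0) stop("labels contain no TP")
  cuts <- sort(unique(scores), decreasing = TRUE)
  # TPR is non-decreasing as the cut is lowered; take the highest cut meeting
  # the target
  n_tp_ge <- vapply(cuts, function(t) sum(tp_scores >= t), integer(1))
  tpr <- n_tp_ge / length(tp_scores)
  ok <- which(tpr >= target_tpr)
  thr <- cuts[ok[1]]
  list(threshold = thr,
       achieved_tpr = mean(tp_scores >= thr),
       achieved_fpr = if (length(fp_scores)) mean(fp_scores >= thr) else NA_real_,
       target_tpr = target_tpr)
}

#' Attach lenient/strict operating points to a filter model
#'
#' @param model A `filter_model`.
#' @param labeled Labeled data frame used to pick the operating points.
#' @param target_lenient,target_strict TPR targets (defaults 0.9 / 0.7).
#' @return The model with `thresholds$lenient` and `thresholds$strict` set.
#' @export
threshold_filter <- function(model, labeled, target_lenient = 0.9,
                             target_strict = 0.7) {
  scores <- score_calls(model, labeled)
  model$thresholds <- list(
    lenient = select_threshold(scores, labeled$label, target_lenient),
    strict = select_threshold(scores, labeled$label, target_strict))
  stopifnot(model$thresholds$strict$threshold >= model$thresholds$lenient$threshold)
  model
}

#' Apply a thresholded filter to call records
#'
#' Keeps records whose score is at least the tier threshold. The strict
#' output is always a subset of the lenient output.
#'
#' @param records Data frame with the feature columns.
#' @param model A thresholded `filter_model` (see [threshold_filter()]).
#' @param tier `"lenient"` or `"strict"`.
#' @return The retained rows of `records`, with a `score` column added.
#' @export
apply_filter <- function(records, model, tier = c("lenient", "strict")) {
  tier <- match.arg(tier)
  if (is.null(model$thresholds[[tier]])) stop("model has no ", tier, " threshold")
  s <- score_calls(model, records)
  out <- records[s >= model$thresholds[[tier]]$threshold, , drop = FALSE]
  out$score <- s[s >= model$thresholds[[tier]]$threshold]
  out
}

## The 16 Mendelian-consistent (father, mother, child) genotype triplets for
## a biallelic site, i.e. those where the child's genotype can be formed from
## one allele of each parent.
.MENDEL_CONSISTENT <- c(
  "0/0|0/0|0/0",
  "0/0|0/1|0/0", "0/0|0/1|0/1",
  "0/0|1/1|0/1",
  "0/1|0/0|0/0", "0/1|0/0|0/1",
  "0/1|0/1|0/0", "0/1|0/1|0/1", "0/1|0/1|1/1",
  "0/1|1/1|0/1", "0/1|1/1|1/1",
  "1/1|0/0|0/1",
  "1/1|0/1|0/1", "1/1|0/1|1/1",
  "1/1|1/1|1/1")

#' Mendelian consistency of a genotype triplet
#'
#' @param father,mother,child Genotype strings in {"0/0","0/1","1/1","./."};
#'   vectorized. Any missing genotype yields NA.
#' @return Logical vector: TRUE when the child's genotype can be formed from
#'   one allele of each parent.
#' @export
mendelian_consistent <- function(father, mother, child) {
  key <- paste(father, mother, child, sep = "|")
  out <- key %in% .MENDEL_CONSISTENT
  out[father == "./." | mother == "./." | child == "./."] <- NA
  out
}

#' Mendelian discordance rate over a trio genotype table
#'
#' Fraction of complete sites (no missing genotype) whose triplet is
#' Mendelian-inconsistent. Missing sites are excluded from numerator and
#' denominator by default; `missing_as_discordant = TRUE` instead counts any
#' site with a missing genotype as discordant.
#'
#' @param trios Data frame with `father`, `mother`, `child` genotype columns.
#' @param missing_as_discordant Alternative missing-data convention.
#' @return List: `rate`, `n_complete`, `n_discordant`.
#' @export
mendelian_discordance <- function(trios, missing_as_discordant = FALSE) {
  cons <- mendelian_consistent(trios$father, trios$mother, trios$child)
  if (missing_as_discordant) {
    n <- length(cons)
    disc <- sum(!cons, na.rm = TRUE) + sum(is.na(cons))
  } else {
    n <- sum(!is.na(cons))
    disc <- sum(!cons, na.rm = TRUE)
  }
  if (n == 0) stop("no complete sites; discordance rate undefined")
  list(rate = disc / n, n_complete = n, n_discordant = disc)
}

#' Exact biallelic Hardy-Weinberg equilibrium test
#'
#' Exact conditional test by enumeration of heterozygote configurations given
#' the minor-allele count (two-sided by probability mass; no mid-p
#' correction).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  n_AA <- as.integer(n_AA); n_Aa <- as.integer(n_Aa); n_aa <- as.integer(n_aa)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(1)
  n_a <- 2L * n_aa + n_Aa                       # minor-ish allele count
  if (n_a > n) return(hwe_exact_test(n_aa, n_Aa, n_AA))
  # heterozygote count must share parity with the allele count
  hets <- seq(n_a %% 2L, n_a, by = 2L)
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    AA <- n - aa - h
    lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[hets == n_Aa]
  sum(p[p <= p_obs + 1e-12])
}

#' Reference-panel postfilters
#'
#' Applies, in order, the four panel postprocessing removal rules:
#' \enumerate{
#'   \item singleton variants (allele count 1);
#'   \item duplicate short variants already represented in the SV callset
#'     (a short variant sharing (chrom, pos) with an SV record);
#'   \item short variants with AF < 0.5\% lying more than 25 kbp from any SV;
#'   \item positionally conflicting calls (records sharing an identical
#'     (chrom, pos); the highest-AF record is kept).
#' }
#'
#' @param variants Position-sorted data frame with columns `variant_id`,
#'   `chrom`, `pos`, `type` (`"SV"` or a short-variant type), `allele_count`,
#'   `af`.
#' @param af_min Rule-3 AF cutoff (default 0.005).
#' @param sv_dist Rule-3 distance cutoff in bp (default 25000).
#' @return List: `retained` (filtered table) and `removal_log` (data frame
#'   `variant_id`, `rule`).
#' @export
panel_postfilter <- function(variants, af_min = 0.005, sv_dist = 25000) {
  v <- variants
  log <- list()
  drop <- function(idx, rule) {
    if (length(idx) == 0) return(invisible())
    log[[length(log) + 1L]] <<- data.frame(variant_id = v$variant_id[idx],
                                           rule = rule, stringsAsFactors = FALSE)
    v <<- v[-idx, , drop = FALSE]
  }
  # rule 1: singletons
  drop(which(v$allele_count == 1L), 1L)
  # rule 2: short variants duplicated by an SV at the same position
  sv_key <- paste(v$chrom[v$type == "SV"], v$pos[v$type == "SV"])
  drop(which(v$type != "SV" & paste(v$chrom, v$pos) %in% sv_key), 2L)
  # rule 3: rare short variants far from any SV
  sv_pos <- v[v$type == "SV", c("chrom", "pos")]
  nearest_sv <- vapply(seq_len(nrow(v)), function(i) {
    p <- sv_pos$pos[sv_pos$chrom == v$chrom[i]]
    if (length(p) == 0) Inf else min(abs(p - v$pos[i]))
  }, numeric(1))
  drop(which(v$type != "SV" & v$af < af_min & nearest_sv > sv_dist), 3L)
  # rule 4: positional conflicts; keep the highest-AF record
  key <- paste(v$chrom, v$pos)
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys)) {
    kill <- unlist(lapply(dup_keys, function(k) {
      i <- which(key == k)
      i[-which.max(v$af[i])]
    }))
    drop(sort(kill), 4L)
  }
  removal_log <- if (length(log)) do.call(rbind, log) else
    data.frame(variant_id = character(), rule = integer(),
               stringsAsFactors = FALSE)
  list(retained = v, removal_log = removal_log)
}

#' Imputation-cohort QC filter
#'
#' A variant is retained iff mean genotype posterior >= 0.7, exact HWE
#' p >= 1e-5, allele-frequency fold change between panel and imputed cohorts
#' < 1.5, carrier concordance >= 70\%, and at least 10 carriers. An AF of 0
#' in one cohort with a nonzero AF in the other is an infinite fold change
#' and is removed. If genotype counts (`n_AA`, `n_Aa`, `n_aa`) are present
#' the HWE p-value is computed by [hwe_exact_test()]; otherwise an `hwe_p`
#' column is used directly.
#'
#' @param table A cohort QC table (see [gen_cohort_qc_table()]).
#' @param thresholds Named list overriding `gp_min` (0.7), `hwe_min` (1e-5),
#'   `af_fold_max` (1.5), `conc_min` (0.7), `carriers_min` (10).
#' @return List: `retained` (variant ids), `removed` (data frame
#'   `variant_id`, `rule`), `rule_counts` (named removal counts; a variant
#'   can trip several rules).
#' @export
apply_phewas_qc <- function(table, thresholds = list()) {
  thr <- utils::modifyList(list(gp_min = 0.7, hwe_min = 1e-5,
                                af_fold_max = 1.5, conc_min = 0.7,
                                carriers_min = 10L), thresholds)
  if (all(c("n_AA", "n_Aa", "n_aa") %in% names(table))) {
    hwe_p <- mapply(hwe_exact_test, table$n_AA, table$n_Aa, table$n_aa)
  } else {
    hwe_p <- table$hwe_p
  }
  a <- table$af_panel; b <- table$af_imputed
  fold <- ifelse(a == 0 & b == 0, 1,
                 ifelse(a == 0 | b == 0, Inf, pmax(a / b, b / a)))
  fails <- cbind(
    gp = table$mean_gp < thr$gp_min,
    hwe = hwe_p < thr$hwe_min,
    af = fold >= thr$af_fold_max - 1e-9,  # guard binary-decimal rounding

    conc = table$carrier_concordance < thr$conc_min,
    carriers = table$n_carriers < thr$carriers_min)
  removed_any <- rowSums(fails) > 0
  removed <- do.call(rbind, lapply(colnames(fails), function(r) {
    ids <- table$variant_id[fails[, r]]
    data.frame(variant_id = ids, rule = rep(r, length(ids)),
               stringsAsFactors = FALSE)
  }))
  list(retained = table$variant_id[!removed_any],
       removed = removed,
       rule_counts = colSums(fails))
}
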
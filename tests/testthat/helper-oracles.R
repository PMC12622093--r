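# Independent oracles used across the suite. Each is a deliberately naive
# computation (brute force, enumeration, exhaustive scan) kept separate from
# the package's implementation path.

# Longest pure run by quadratic scan over all (start, end) unit windows.
oracle_longest_pure_run <- function(units, motif) {
  n <- length(units)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(units[i:j] == motif)) best <- max(best, j - i + 1L)
    }
  }
  best
}

# Best tile label by exhaustive ungapped mismatch scan over every offset of
# every reference (indel-free generators make this the alignment argmax in
# non-tie cases). Returns NA on a tie for minimum mismatches across labels.
oracle_tile_label <- function(tile, refs) {
  labs <- names(refs)
  best_mm <- vapply(labs, function(lab) {
    subj <- Biostrings::DNAString(refs[[lab]])
    k <- nchar(tile)
    m <- length(subj)
    if (m < k) return(Inf)
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(tile), subj,
                                      starting.at = 1:(m - k + 1),
                                      with.indels = FALSE)
    min(mm)
  }, numeric(1))
  o <- order(best_mm)
  if (best_mm[o[1]] == best_mm[o[2]]) return(NA_character_)
  labs[o[1]]
}

# Mendelian consistency by enumerating the four allele transmissions.
oracle_mendel <- function(father, mother, child) {
  alleles <- function(g) as.integer(strsplit(g, "/", fixed = TRUE)[[1]])
  fa <- alleles(father); mo <- alleles(mother); ch <- sort(alleles(child))
  for (a in fa) for (b in mo) {
    if (identical(sort(c(a, b)), ch)) return(TRUE)
  }
  FALSE
}

# Expected fraction of random genotype substitutions that are detectable as
# Mendelian-inconsistent, by full enumeration over parent pairs, transmitted
# child genotypes, and the two possible replacement genotypes.
oracle_detectable_error_fraction <- function(p) {
  gts <- c("0/0", "0/1", "1/1")
  gt_probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  transmit_probs <- function(g) switch(g,
    "0/0" = c(1, 0), "0/1" = c(0.5, 0.5), "1/1" = c(0, 1))  # P(allele 0), P(allele 1)
  total <- 0
  for (fi in 1:3) for (mi in 1:3) {
    pf <- transmit_probs(gts[fi]); pm <- transmit_probs(gts[mi])
    child_probs <- c(pf[1] * pm[1],                     # 0/0
                     pf[1] * pm[2] + pf[2] * pm[1],     # 0/1
                     pf[2] * pm[2])                     # 1/1
    for (ci in 1:3) {
      if (child_probs[ci] == 0) next
      repl <- setdiff(1:3, ci)
      for (ri in repl) {
        inconsistent <- !oracle_mendel(gts[fi], gts[mi], gts[ri])
        total <- total + gt_probs[fi] * gt_probs[mi] * child_probs[ci] *
          0.5 * inconsistent
      }
    }
  }
  total
}

# Threshold selection by brute-force sweep over every distinct score cut.
oracle_threshold <- function(scores, labels, target) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  tp <- scores[labels == "TP"]
  for (t in cuts) {
    if (mean(tp >= t) >= target) return(t)
  }
  min(cuts)
}

# Rank-statistic AUC (Mann-Whitney), independent of any model internals.
rank_auc <- function(scores, labels) {
  pos <- scores[labels == "TP"]; neg <- scores[labels == "FP"]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

random_units <- function(n, motif, n_interruptions, alt = "AGG") {
  u <- rep(motif, n)
  if (n_interruptions > 0) {
    idx <- sample(n, min(n_interruptions, n))
    u[idx] <- alt
  }
  u
}
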
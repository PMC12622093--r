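#' Specify a simulated labeled SV callset
#'
#' Label-conditional feature model for candidate SV calls: binary TP/FP
#' labels are drawn at `prevalence_true`; allele depth and allele balance are
#' label-conditional Gaussians, variant length is log-normal, and multi-caller
#' support is `1 + Binomial(2, p)` with the logit of `p` shifted for true
#' calls. Effect sizes are standardized (TP means shifted by
#' `effect * sd * noise_sd` from the FP means). The defaults are the
#' simulation conditions used throughout the package's threshold experiments:
#' 60% true-call prevalence and standardized effects of 1.5 on all four
#' features.
#'
#' @param n_calls Number of calls (>= 100 for threshold experiments).
#' @param prevalence_true Fraction of true calls, strictly inside (0, 1).
#' @param effect_sizes Named or positional numeric vector of standardized
#'   effects for (allele_depth, allele_balance, length, caller_support).
#' @param noise_sd Positive multiplier on the base feature standard
#'   deviations.
#' @param seed Integer seed.
#' @return Object of class `sv_sim_spec`.
#' @export
sv_sim_spec <- function(n_calls = 10000L, prevalence_true = 0.6,
                        effect_sizes = c(allele_depth = 1.5,
                                         allele_balance = 1.5,
                                         length = 1.5,
                                         caller_support = 1.5),
                        noise_sd = 1, seed = 1L) {
  n_calls <- as.integer(n_calls)
  if (n_calls < 100) stop("n_calls must be >= 100 for threshold experiments")
  if (prevalence_true <= 0 || prevalence_true >= 1) {
    stop("prevalence_true must be strictly inside (0, 1)")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  stopifnot(length(effect_sizes) == 4)
  names(effect_sizes) <- c("allele_depth", "allele_balance", "length",
                           "caller_support")
  structure(list(n_calls = n_calls, prevalence_true = prevalence_true,
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sv_sim_spec")
}

#' Generate a labeled SV feature table
#'
#' @param spec An [sv_sim_spec()].
#' @return Data frame with columns `call_id`, `chrom`, `pos`, `svtype`,
#'   `svlen`, `allele_depth`, `allele_balance`, `length`, `caller_support`,
#'   and truth `label` in {"TP", "FP"}. Pure function of the spec (seed
#'   included). Zero effect sizes are flagged non-separable via the
#'   `separable` attribute.
#' @export
gen_sv_feature_table <- function(spec = sv_sim_spec()) {
  stopifnot(inherits(spec, "sv_sim_spec"))
  e <- spec$effect_sizes
  withr::with_seed(spec$seed, {
    n <- spec$n_calls
    is_tp <- runif(n) < spec$prevalence_true
    sd_depth <- 3 * spec$noise_sd
    sd_bal <- 0.12 * spec$noise_sd
    sd_loglen <- 1 * spec$noise_sd
    depth <- pmax(0, rnorm(n, 10 + ifelse(is_tp, e["allele_depth"] * sd_depth, 0),
                           sd_depth))
    bal <- pmin(1, pmax(0, rnorm(n, 0.28 + ifelse(is_tp, e["allele_balance"] * sd_bal, 0),
                                 sd_bal)))
    len <- round(exp(rnorm(n, log(300) + ifelse(is_tp, e["length"] * sd_loglen, 0),
                           sd_loglen))) + 50L
    p_sup <- plogis(qlogis(0.25) + ifelse(is_tp, e["caller_support"], 0))
    support <- 1L + rbinom(n, 2L, p_sup)
    svtype <- sample(c("INS", "DEL"), n, replace = TRUE)
    pos <- sort(sample.int(2e8L, n))
    out <- data.frame(
      call_id = sprintf("call%06d", seq_len(n)),
      chrom = "chr1", pos = pos, svtype = svtype,
      svlen = ifelse(svtype == "DEL", -len, len),
      allele_depth = depth, allele_balance = bal, length = len,
      caller_support = support,
      label = ifelse(is_tp, "TP", "FP"), stringsAsFactors = FALSE)
    attr(out, "separable") <- any(e != 0)
    attr(out, "spec") <- spec
    out
  })
}

#' Specify a simulated trio genotype table
#'
#' @param n_sites Number of biallelic sites.
#' @param allele_frequency Alternate allele frequency, strictly inside (0, 1).
#' @param planted_error_rate Fraction of child genotypes replaced by a
#'   uniformly random different genotype, in `[0, 1)`.
#' @param seed Integer seed.
#' @return Object of class `trio_sim_spec`.
#' @export
trio_sim_spec <- function(n_sites, allele_frequency = 0.3,
                          planted_error_rate = 0, seed = 1L) {
  if (allele_frequency <= 0 || allele_frequency >= 1) {
    stop("allele_frequency must be strictly inside (0, 1)")
  }
  if (planted_error_rate < 0 || planted_error_rate >= 1) {
    stop("planted_error_rate must be in [0, 1)")
  }
  structure(list(n_sites = as.integer(n_sites),
                 allele_frequency = allele_frequency,
                 planted_error_rate = planted_error_rate,
                 seed = as.integer(seed)),
            class = "trio_sim_spec")
}

.GTS <- c("0/0", "0/1", "1/1")

hwe_genotypes <- function(n, p) {
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  sample(.GTS, n, replace = TRUE, prob = probs)
}

transmit <- function(gt) {
  # one allele drawn uniformly from the parent's pair
  a <- ifelse(gt == "0/0", 0L, ifelse(gt == "1/1", 1L,
              rbinom(length(gt), 1L, 0.5)))
  a
}

#' Generate trio genotypes with a planted Mendelian error rate
#'
#' Parents are drawn at Hardy-Weinberg proportions from the allele frequency;
#' the child receives one uniformly chosen allele from each parent; then a
#' `planted_error_rate` fraction of child genotypes is replaced by a
#' uniformly random *different* genotype. Note only a subset of such random
#' substitutions is Mendelian-inconsistent, so the downstream discordance
#' rate is the detectable fraction of the planted rate, not the planted rate
#' itself.
#'
#' @param spec A [trio_sim_spec()].
#' @return Data frame: `site`, `father`, `mother`, `child`, `error_planted`.
#' @export
gen_trio_genotypes <- function(spec) {
  stopifnot(inherits(spec, "trio_sim_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_sites
    father <- hwe_genotypes(n, spec$allele_frequency)
    mother <- hwe_genotypes(n, spec$allele_frequency)
    child_alleles <- transmit(father) + transmit(mother)
    child <- .GTS[child_alleles + 1L]
    err <- runif(n) < spec$planted_error_rate
    if (any(err)) {
      child[err] <- vapply(child[err], function(g) sample(setdiff(.GTS, g), 1L),
                           character(1))
    }
    data.frame(site = seq_len(n), father = father, mother = mother,
               child = child, error_planted = err, stringsAsFactors = FALSE)
  })
}

#' Generate a cohort imputation-QC table with planted violations
#'
#' Builds a per-variant QC table (mean genotype posterior, genotype counts
#' for the HWE test, panel/imputed allele frequencies, carrier concordance,
#' carrier count) in which exactly the requested numbers of variants violate
#' each QC rule; violating sets are disjoint and marked in truth columns
#' (`fail_gp`, `fail_hwe`, `fail_af`, `fail_conc`, `fail_carriers`).
#'
#' @param n_variants Number of variants.
#' @param planted_violations Named integer vector with any of
#'   `gp`, `hwe`, `af`, `conc`, `carriers`; the sum must not exceed
#'   `n_variants`.
#' @param seed Integer seed.
#' @param n_genotyped Individuals behind the genotype counts for HWE.
#' @return Data frame of class `cohort_qc_table`.
#' @export
gen_cohort_qc_table <- function(n_variants,
                                planted_violations = c(gp = 0L, hwe = 0L,
                                                       af = 0L, conc = 0L,
                                                       carriers = 0L),
                                seed = 1L, n_genotyped = 400L) {
  n_variants <- as.integer(n_variants)
  pv <- c(gp = 0L, hwe = 0L, af = 0L, conc = 0L, carriers = 0L)
  pv[names(planted_violations)] <- as.integer(planted_violations)
  if (sum(pv) > n_variants) stop("planted violation counts exceed n_variants")
  if (n_variants == 0) {
    out <- data.frame(variant_id = character(), mean_gp = numeric(),
                      n_AA = integer(), n_Aa = integer(), n_aa = integer(),
                      af_panel = numeric(), af_imputed = numeric(),
                      carrier_concordance = numeric(), n_carriers = integer(),
                      fail_gp = logical(), fail_hwe = logical(),
                      fail_af = logical(), fail_conc = logical(),
                      fail_carriers = logical(), stringsAsFactors = FALSE)
    class(out) <- c("cohort_qc_table", "data.frame")
    return(out)
  }
  withr::with_seed(seed, {
    ids <- sprintf("var%05d", seq_len(n_variants))
    # passing baseline
    mean_gp <- runif(n_variants, 0.8, 1)
    af_panel <- runif(n_variants, 0.05, 0.45)
    af_imputed <- af_panel * runif(n_variants, 1 / 1.2, 1.2)
    conc <- runif(n_variants, 0.8, 1)
    carriers <- sample(20:200, n_variants, replace = TRUE)
    # HWE-consistent genotype counts at each variant's panel AF
    n_AA <- integer(n_variants); n_Aa <- integer(n_variants)
    n_aa <- integer(n_variants)
    for (i in seq_len(n_variants)) {
      repeat {
        g <- table(factor(hwe_genotypes(n_genotyped, af_panel[i]), levels = .GTS))
        if (hwe_exact_test(g[1], g[2], g[3]) >= 1e-5) break
      }
      n_AA[i] <- g[1]; n_Aa[i] <- g[2]; n_aa[i] <- g[3]
    }
    # disjoint violating sets
    pool <- sample.int(n_variants)
    take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
    i_gp <- take(pv["gp"]); i_hwe <- take(pv["hwe"]); i_af <- take(pv["af"])
    i_conc <- take(pv["conc"]); i_car <- take(pv["carriers"])
    mean_gp[i_gp] <- runif(length(i_gp), 0.3, 0.69)
    if (length(i_hwe)) {                      # all-het excess: exact p ~ 0
      n_Aa[i_hwe] <- n_genotyped; n_AA[i_hwe] <- 0L; n_aa[i_hwe] <- 0L
    }
    af_imputed[i_af] <- af_panel[i_af] * runif(length(i_af), 1.6, 3)
    conc[i_conc] <- runif(length(i_conc), 0.2, 0.69)
    carriers[i_car] <- sample(1:9, length(i_car), replace = TRUE)
    out <- data.frame(
      variant_id = ids, mean_gp = mean_gp,
      n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
      af_panel = af_panel, af_imputed = af_imputed,
      carrier_concordance = conc, n_carriers = carriers,
      fail_gp = seq_len(n_variants) %in% i_gp,
      fail_hwe = seq_len(n_variants) %in% i_hwe,
      fail_af = seq_len(n_variants) %in% i_af,
      fail_conc = seq_len(n_variants) %in% i_conc,
      fail_carriers = seq_len(n_variants) %in% i_car,
      stringsAsFactors = FALSE)
    class(out) <- c("cohort_qc_table", "data.frame")
    out
  })
}
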
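# locuskit

Locus-resolution analyses for long-read haplotypes: tandem-repeat allele
characterization, CYP2D6–CYP2D7 structural haplotyping with star-allele and
metabolizer inference, and the filtering/QC layer used around multi-caller
structural-variant (SV) callsets.

Population-scale long-read studies resolve loci that short reads cannot:
triplet-repeat tracts whose length *and* purity drive disease risk, the
CYP2D6 pharmacogene with its duplications, deletions and CYP2D7 fusion
alleles, and hundreds of thousands of SVs called by multiple algorithms at
mid-pass (~8x) coverage. locuskit packages the computational core of those
analyses for anyone working with assembled haplotypes or SV call tables —
clinical repeat thresholds, k-mer paralog painting, star-allele matching
under the all-defining-variants rule, ROC-targeted call filtering, Mendelian
trio QC, and imputation-cohort QC — together with seeded synthetic
generators that stand in for controlled-access cohort data so every stage is
testable offline.

## The methods in brief

* **Tandem repeats.** An allele sequence is decomposed into motif units; the
  package reports total units, the longest pure run
  `max { j − i + 1 : units i..j are all exact motif copies }`, and all
  interruptions. Clinical classification uses printed boundaries (FMR1
  premutation ≥ 55 CGG; HTT intermediate 27–35, reduced-penetrance ≥ 36 CAG;
  ATXN3 pathogenic > 55 CAG; FMR1 3′ instability tiers 25–33 / ≥ 34
  uninterrupted CGG). Per-locus variability is the unscaled MAD of allele
  length plus type-7 percentiles of the pure run; loci whose excess
  `p99 − median` reaches the minimum over known pathogenic loci are nominated
  as candidates.
* **CYP2D6 structure.** Haplotypes are cut into 100 bp tiles, each locally
  aligned (+1/−1, gap −2/−1) to D6/D7/spacer references and labeled by
  argmax score with a `min(60, 2·Δ)` confidence proxy; run-length
  segmentation with a 3-tile minimum run yields gene copies, hybrids
  (`CYP2D6::7`-style fusions, breakpoint at the first switched tile), and
  the configuration class (canonical / duplication / deletion / hybrid).
* **Star alleles.** Haplotype variants are derived from a global alignment
  and normalized (left-aligned, parsimonious); a definition qualifies only
  when all its defining variants are present; candidates are ranked by
  matched count, then alignment score against the allele sequence, then
  fewest extras. Diplotype activity scores map to CPIC metabolizer bins
  (0 → PM, (0,1] → IM, (1,2.25] → NM, > 2.25 → UM).
* **SV filtering/QC.** Calls are labeled against a truth set
  (distance ≤ 500 bp, size similarity ≥ 0.7), scored by a seeded
  gradient-boosted classifier on allele depth, allele balance, length and
  caller support, and thresholded at target TPRs 0.9 (lenient) and 0.7
  (strict). Mendelian discordance, the four reference-panel postfilters, and
  the five-rule imputation QC (GP ≥ 0.7, exact HWE p ≥ 1e-5, AF fold-change
  < 1.5, carrier concordance ≥ 70%, ≥ 10 carriers) complete the layer.

## Worked example

```r
library(locuskit)

# An FMR1-style premutation allele: 60 CGG units with AGG interruptions at
# unit indices 9 and 19, then an uninterrupted 3' tract
spec   <- repeat_spec("FMR1", "CGG", 60,
                      data.frame(unit_index = c(9, 19), motif = "AGG"))
allele <- gen_repeat_allele(spec)
a <- characterize_allele(allele$repeat_sequence, "CGG", canonical = "AGG")
a$total_units               # 60   (AGG units count toward FMR1 length)
a$longest_pure_run          # 40   (units 20..59 after the last AGG)
classify_allele("FMR1", a)  # "premutation"  (>= 55 units)
fmr1_instability_tier(a)    # "high"         (3' pure run 40 >= 34)

# ROC-targeted SV filtering on a simulated labeled callset
tab   <- gen_sv_feature_table(sv_sim_spec(n_calls = 10000, seed = 1))
model <- threshold_filter(train_filter(tab, seed = 1), tab)
unlist(model$thresholds$lenient)
#>  threshold achieved_tpr achieved_fpr   target_tpr
#>  0.7363341    0.9000663    0.0484115    0.9000000
unlist(model$thresholds$strict)
#>   threshold achieved_tpr achieved_fpr   target_tpr
#> 0.952585697 0.700033146  0.008320726   0.700000000
```

The lenient operating point keeps 90.01% of true calls at a 4.8% false
positive rate; the strict point trades recall (70.00%) for an FPR under 1%,
and its output is always a subset of the lenient callset.

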
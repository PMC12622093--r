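---
title: "Methods: locus-resolution analyses in locuskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-resolution analyses in locuskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locuskit)
```

locuskit implements, as reusable and fully testable components, the
locus-resolution procedures that population-scale long-read studies apply to
their assembled haplotypes: tandem-repeat allele characterization and
candidate-locus nomination, paralog painting of the CYP2D6–CYP2D7 region with
star-allele and metabolizer inference, and the filtering/QC machinery wrapped
around multi-caller structural-variant (SV) callsets. Because the cohorts such
studies analyze are controlled-access, every input the pipeline consumes can
be produced by a seeded synthetic generator carrying ground-truth labels; the
generators are first-class, tested code, and every downstream claim in the
test suite is scored against their planted truth.

## Tandem-repeat characterization

A repeat allele is decomposed into consecutive, non-overlapping motif-length
units. When the supplied repeat region is not an exact multiple of the motif
length — a situation the upstream genotyper's boundary calls can produce —
the register (start offset within one motif length) maximizing the number of
exact motif units is chosen, and the sub-motif leading/trailing remainders
are dropped and recorded. No convention for this is standard; the choice is
declared here and carried in the decomposition object.

Three per-allele statistics drive everything downstream:

* **total units** — the unit count including interruption units. For FMR1
  this matches the clinical convention in which AGG interruptions count
  toward the repeat length. For HTT the package expects the supplied repeat
  region to be the pure CAG tract (plus any internal interruptions) and to
  exclude the downstream CAA-CAG/CCG cassette, because the clinical CAG-count
  thresholds (27, 36) assume that convention.
* **longest pure run** — the maximal contiguous run of exact motif copies,
  the quantity most predictive of instability.
* **interruptions** — every non-motif unit, flagged canonical when it belongs
  to the locus's recognized interruption set (AGG for FMR1 CGG tracts, CAA
  for HTT CAG tracts).

Classification uses the packaged boundary tables: FMR1 premutation at ≥ 55
units (full mutation above 200); HTT normal < 27, intermediate 27–35,
reduced-penetrance ≥ 36; ATXN3 pathogenic strictly above 55. The FMR1
instability tier is read off the uninterrupted CGG run at the 3′ end of the
tract — the segment distal to the last interruption — with 25–33 units the
moderate tier and ≥ 34 the high tier. All boundaries are inclusive exactly as
printed, which the test suite asserts at each boundary and its ±1 neighbors.

Per-locus variability combines the unscaled median absolute deviation of
allele length (in units) with the 50th and 99th percentiles of the longest
pure run. Quantiles use linear interpolation between order statistics
(type 7); the convention is recorded in the output's attributes because the
candidate rule below consumes the difference of two quantiles. Whether the
MAD should be computed over total allele length or pure-segment length is
genuinely ambiguous; the default is total length with `mad_on = "pure"`
available.

Candidate nomination is a declared, explicit rule rather than a visual one: a
locus is a candidate when it is not a known pathogenic locus and its excess
statistic (p99 − median of the longest pure run) reaches the *minimum* excess
among the known pathogenic loci present in the table — the least stringent
cut that still separates every known locus. The threshold is reported with
the output so analysts can tighten it.

## CYP2D6–CYP2D7 structure

Haplotypes over the locus are divided into non-overlapping 100 bp tiles
(overlapping 100-mers would cost ~100× the alignment work for no labeling
gain; the stride is configurable), and every tile is locally aligned against
each labeled reference (gene surrogates for CYP2D6 and CYP2D7 plus the
intergenic spacer) under unit costs: match +1, mismatch −1, gap open −2, gap
extend −1. The tile takes the argmax label; a MAPQ-like proxy
`min(60, 2 × (best − second best))` expresses confidence. With these costs a
single discriminating base separates scores by 2, so the default ambiguity
margin of 2 means "label unless exactly tied". Tiles scoring below 40 — about
the level a random 100-mer reaches against an unrelated reference — are
`UNALIGNED`.

Segmentation run-length encodes tile labels, absorbing runs shorter than
3 tiles (300 bp) to suppress single-tile flicker from paralog homology, and
groups consecutive gene-label runs between spacer runs into gene copies. A
copy whose labels switch mid-body with at least 3 tiles of support on both
sides becomes a hybrid (`X::Y`), with the breakpoint placed at the first tile
of the new label — the resolution is inherently one tile, and recovery tests
require agreement within ±2 tiles of planted truth. Hybrids contribute to
neither pure-gene copy number and are tallied separately, matching how
published structure counts report hybrids apart from duplications and
deletions. The configuration class is: hybrid if any hybrid copy exists, else
deletion when no CYP2D6 copy remains, duplication at two or more CYP2D6
copies, canonical for the single-copy D6+D7 arrangement.

The synthetic reference surrogates are seeded random sequences with the D7
paralog derived from D6 by i.i.d. substitution at rate 0.05, mirroring the
~94–95% identity of the real paralogs. Generated loci are clean consensus
sequences by default; a substitution-noise knob (used at 0.01 in the recovery
tests) emulates residual consensus error. What the generator does *not*
emulate: real flanking segmental-duplication structure (REP elements),
assembly collapse over duplications, and indel-containing divergence — so
passing recovery tests demonstrate correctness of the painting/segmentation
logic, not robustness to assembly artifacts.

## Star alleles, diplotypes, and metabolizer phenotype

Star-allele calling aligns the haplotype globally to the gene reference,
derives its variants from the alignment walk, and normalizes every variant to
a left-aligned parsimonious representation so indel representation cannot
break set comparisons. A definition is a candidate only when **all** of its
defining variants are present on the haplotype. Among candidates the call
maximizes, in order: matched defining-variant count, the global alignment
score of the haplotype against the candidate's allele sequence (reference
with its defining variants applied), and fewest extra variants. The
precedence between variant matches and alignment score is not externally
fixed; the package puts the matched count first because the all-variants rule
makes it the discriminating signal, and the ordering is configurable in
principle by re-scoring candidates. Exact ties are surfaced
(`ambiguous = TRUE` with all tied names), never silently broken. Suballeles
(e.g. \*4.013) are reported at full resolution but aggregate to their core
star for activity scoring.

Novel variants are the set difference between haplotype variants and the
assigned definition's variants. For protein-level interpretation, exon
intervals are supplied explicitly (no gene predictor is run), projected
through the alignment to build the haplotype CDS, and translated with the
standard code; changes are reported as RefAA-Position-AltAA with nonsense and
frameshift flagged.

Diplotype activity is the sum of the two core-allele activity values from the
packaged table (CPIC-derived defaults for the packaged stars, overridable by
file), binned as: 0 → poor metabolizer; (0, 1] → intermediate; (1, 2.25] →
normal; above 2.25 → ultrarapid. Any ambiguous or unassigned haplotype, or a
star missing from the activity table, yields an indeterminate phenotype with
a reason. Multi-caller reconciliation takes the most frequent identical call
string when its count reaches 2; ties and sub-threshold majorities are
indeterminate.

The packaged definitions live on a synthetic ~1.9 kb gene surrogate (a seeded
sequence with three exons forming a valid CDS); they are shaped like
PharmVar tables but are synthetic, which the round-trip tests exploit: every
packaged definition regenerated into a haplotype must be called back exactly,
with planted extras recovered as the novel set.

## SV filtering and cohort QC

Candidate calls are labeled against a truth set with a distance/size
predicate (start distance ≤ 500 bp, size similarity ≥ 0.7 — the defaults of
the merging tool this layer stands in for), assigned greedily nearest-first
with each truth record consumed once; on randomized sets the greedy matching
agrees with an optimal bipartite assignment in ≥ 99% of calls.

The scorer is a gradient-boosted tree classifier (single-threaded, seeded,
hence bit-reproducible) over the four genotyping features: allele depth,
allele balance, variant length, multi-caller support. Operating points are
chosen by the rule "largest score cut whose TPR on the labeled data still
meets the target", i.e. the most specific point meeting the target, for a
lenient (TPR 0.9) and a strict (TPR 0.7) tier; the strict callset is by
construction a subset of the lenient one. The synthetic callset generator
draws label-conditional Gaussians for depth and balance, a log-normal for
length, and a shifted binomial for caller support; its defaults (10,000
calls, prevalence 0.6, standardized effects 1.5) are the fixed simulation
conditions for the threshold experiments. With all effects zeroed the
held-out AUC is ~0.5 and a TPR-0.9 threshold chosen on held-out scores
retains ~90% of both classes — the filter claims no specificity without
signal.

Mendelian discordance is the fraction of complete trio sites whose genotype
triplet cannot be formed by transmitting one allele from each parent; the
16 consistent triplets are hardcoded and checked against a transmission
enumeration in the tests. Sites with any missing genotype are excluded from
both numerator and denominator (a flag switches to counting them as
discordant). Note the trio generator plants errors as uniformly random
*different* genotypes, of which only a fraction is detectable as
Mendelian-inconsistent; the tests compare against that enumerable detectable
fraction, not the planted rate.

The reference-panel postfilters apply four removal rules in order:
singletons; short variants duplicating an SV record at the same position;
short variants with AF < 0.5% more than 25 kbp from any SV; and positionally
conflicting records, where the highest-AF record at a duplicated position is
kept. The second and fourth rules are operationalizations (the source
procedures do not specify tie-breaking); every removal is logged with its
rule id. Cohort imputation QC retains a variant only when mean genotype
posterior ≥ 0.7, exact Hardy–Weinberg p ≥ 1e-5 (a hand-implemented exact
biallelic test by heterozygote-configuration enumeration, no mid-p), AF fold
change between panel and imputed cohort < 1.5 (an AF of zero on one side is
an infinite fold change; the comparison carries a 1e-9 guard against
binary-decimal rounding at the printed boundary), carrier concordance ≥ 70%,
and ≥ 10 carriers — boundaries inclusive exactly as the printed inequalities
imply.

## Problem sizes, tolerances, and reproducibility

Every generator is a pure function of its specification, seed included, and
the package-level experiments run at fixed sizes chosen to make Monte-Carlo
error small relative to the tolerances tested: 10,000 calls for threshold
targeting (TPR granularity ~1/6,000 against a ±0.02 check), 10,000 trio
sites (3 standard errors against the enumerated expectation), 210 painted
loci across the seven structural classes for ≥ 95% recovery, and 1,000
random alleles for the pure-run oracle sweep. Stochastic assertions compare
against binomial standard errors at those sizes rather than point equality.

Known limitations: repeat decomposition assumes strand-resolved catalog
motifs (no rotation/reverse-complement folding by default); painting assumes
the supplied haplotype spans the locus contiguously; star-allele calling
handles non-CNV haplotypes only (structural configurations are the painting
module's job); and the SV feature model is a deliberately simple parametric
stand-in — conclusions about real callsets require relabeling against a real
truth set.

## The command-line surface

The package is an analysis library: the exported functions above, together
with `scripts/acceptance.R` (which re-runs the classification sweeps and the
simulate→train→threshold experiment from scratch and writes the results as
JSON), are its interface. Readers and writers for FASTA, the BED-like repeat
catalog (with optional 25 bp padding), and a minimal SV VCF subset keep every
artifact in plain text.
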
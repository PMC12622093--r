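Package: locuskit
Title: Locus-Resolution Analysis of Tandem Repeats, CYP2D6 Structure, and
    Structural-Variant Quality Control from Long-Read Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing disease-relevant loci from long-read
    haplotype and assembly sequences. Decomposes tandem-repeat alleles into
    motif units to measure pure-tract lengths and interruptions, classifies
    FMR1/HTT/ATXN3 alleles against clinical repeat-count thresholds, and
    nominates candidate unstable loci from catalog-level variability
    statistics. Paints CYP2D6-CYP2D7 haplotypes with 100 bp tiles labeled by
    best-matching paralog to call structural configurations (duplications,
    deletions, hybrids), assigns star alleles requiring all defining
    variants, and derives CPIC metabolizer phenotypes. Provides the
    structural-variant filtering layer used for multi-caller callsets:
    truth-set labeling, a gradient-boosted scorer with ROC-targeted
    lenient/strict thresholds, Mendelian trio discordance, reference-panel
    postfilters, and imputation-cohort QC. Seeded synthetic-data generators
    produce every input with ground-truth labels so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
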
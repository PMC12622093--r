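#' Generate a star-allele haplotype with planted truth
#'
#' Applies a definition's defining variants plus any extra variants to the
#' gene reference, right-to-left by position, and returns the haplotype with
#' the planted truth. Overlapping variants are an input error.
#'
#' @param definition An [allele_definition()].
#' @param extra_variants Optional variant data frame of additional (novel)
#'   variants to plant.
#' @param reference Gene reference DNA string.
#' @return List: `haplotype`, `truth` (list with `star`, `core`, `defining`,
#'   `extra` variant frames).
#' @export
gen_star_haplotype <- function(definition, extra_variants = NULL,
                               reference = synthetic_pgx_reference()$sequence) {
  stopifnot(inherits(definition, "allele_definition"))
  extra <- extra_variants %||% variant_frame()
  all_v <- rbind(definition$variants, extra)
  hap <- apply_variants(reference, all_v)
  list(haplotype = hap,
       truth = list(star = definition$star, core = definition$core,
                    defining = definition$variants, extra = extra))
}

#' Draw a random missense SNV within the exons of a gene reference
#'
#' Picks a seeded second-codon-position SNV (guaranteed nonsynonymous) inside
#' an exon, avoiding a set of positions (e.g. a definition's variants). Used
#' to plant novel variants for recovery tests.
#'
#' @param reference List from [synthetic_pgx_reference()] (needs `sequence`
#'   and `exons`).
#' @param seed Integer seed.
#' @param avoid Integer vector of 0-based positions to avoid.
#' @return One-row variant data frame.
#' @export
random_missense_variant <- function(reference, seed = 1L, avoid = integer()) {
  ex <- reference$exons
  cds_pos <- unlist(lapply(seq_len(nrow(ex)), function(i) ex$start[i]:(ex$end[i] - 1L)))
  offset_in_cds <- seq_along(cds_pos) - 1L
  # second codon position, not the start/stop codon
  cand <- cds_pos[offset_in_cds %% 3L == 1L &
                  offset_in_cds > 3L & offset_in_cds < length(cds_pos) - 3L]
  cand <- setdiff(cand, avoid)
  withr::with_seed(seed, {
    pos <- sample(cand, 1L)
    ref <- substr(reference$sequence, pos + 1L, pos + 1L)
    alt <- sample(setdiff(DNA_BASES, ref), 1L)
    variant_frame(pos, ref, alt)
  })
}
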
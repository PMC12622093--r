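#' @importFrom stats median quantile rnorm runif rbinom predict setNames plogis qlogis
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. draw over A/C/G/T. All generators route their randomness
#' through the caller's seed (via [withr::with_seed()]), so this helper itself
#' does not touch the seed.
#'
#' @param n Sequence length in bp.
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Random DNA guaranteed not to contain a motif
#'
#' Used for repeat flanks so that the repeat/flank boundary is unambiguous.
#' Resamples until no occurrence of `motif` is present.
#'
#' @param n Length in bp.
#' @param motif Motif to exclude (and its unit-register shifts, implicitly).
#' @keywords internal
random_dna_avoiding <- function(n, motif) {
  for (i in 1:100) {
    s <- random_dna(n)
    if (!grepl(motif, s, fixed = TRUE)) return(s)
  }
  stop("could not generate a ", n, " bp flank free of motif ", motif)
}

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string")
  }
  if (nchar(x) > 0 && grepl("[^ACGT]", x)) {
    stop(what, " contains characters outside {A,C,G,T}")
  }
  invisible(x)
}

#' Apply i.i.d. per-base substitutions to a sequence
#'
#' Every base is replaced, independently with probability `rate`, by a base
#' drawn uniformly from the three alternatives. Used to derive divergent
#' paralog surrogates.
#'
#' @param sequence DNA string.
#' @param rate Per-base substitution probability in `[0, 1]`.
#' @keywords internal
mutate_sequence <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1))
  }
  paste(bases, collapse = "")
}

## ---- variant representation -------------------------------------------------
## A variant is a row (pos, ref, alt): pos is 0-based on the reference,
## ref/alt are allele strings; "" encodes a pure insertion/deletion.

variant_frame <- function(pos = integer(), ref = character(), alt = character()) {
  data.frame(pos = as.integer(pos), ref = as.character(ref),
             alt = as.character(alt), stringsAsFactors = FALSE)
}

variant_key <- function(v) {
  if (nrow(v) == 0) return(character())
  paste0(v$pos, ":", v$ref, ">", v$alt)
}

#' Normalize a variant to a left-aligned, parsimonious representation
#'
#' Trims shared prefixes/suffixes and shifts indels left through repeated
#' context so that representation differences can never break set comparisons
#' between haplotype-derived and defining variants.
#'
#' @param pos 0-based position on the reference.
#' @param ref,alt Allele strings ("" allowed for pure indels).
#' @param reference Full reference sequence (needed for left-shifting indels).
#' @return A one-row variant data frame, or zero rows if ref == alt.
#' @export
normalize_variant <- function(pos, ref, alt, reference) {
  # trim common suffix
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt)) &&
         !(nchar(ref) == 1 && nchar(alt) == 1)) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         !(nchar(ref) == 1 && nchar(alt) == 1)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) return(variant_frame())
  # left-shift pure indels through repeated sequence
  if (nchar(ref) == 0 || nchar(alt) == 0) {
    ins <- nchar(ref) == 0
    seqs <- if (ins) alt else ref
    while (pos > 0) {
      prev <- substr(reference, pos, pos)  # base at 0-based pos-1
      last <- substr(seqs, nchar(seqs), nchar(seqs))
      if (prev != last) break
      seqs <- paste0(prev, substr(seqs, 1L, nchar(seqs) - 1L))
      pos <- pos - 1L
    }
    if (ins) alt <- seqs else ref <- seqs
  }
  variant_frame(pos, ref, alt)
}

#' Apply variants to a reference sequence
#'
#' Variants are applied right-to-left by position so earlier edits cannot
#' shift the coordinates of later ones. Overlapping variants are an error.
#'
#' @param reference Reference DNA string.
#' @param variants Variant data frame (`pos`, `ref`, `alt`; 0-based).
#' @return The edited sequence.
#' @export
apply_variants <- function(reference, variants) {
  if (is.null(variants) || nrow(variants) == 0) return(reference)
  v <- variants[order(variants$pos), , drop = FALSE]
  ends <- v$pos + pmax(nchar(v$ref), 1L)  # "" ref (insertion) still anchors a point
  if (nrow(v) > 1 && any(v$pos[-1] < ends[-nrow(v)])) {
    stop("overlapping variants cannot be applied")
  }
  if (any(v$pos < 0 | v$pos + nchar(v$ref) > nchar(reference))) {
    stop("variant outside reference bounds")
  }
  out <- reference
  for (i in rev(seq_len(nrow(v)))) {
    p <- v$pos[i]
    obs <- substr(out, p + 1L, p + nchar(v$ref[i]))
    if (nchar(v$ref[i]) > 0 && obs != v$ref[i]) {
      stop("ref allele mismatch at 0-based position ", p,
           " (expected ", v$ref[i], ", found ", obs, ")")
    }
    out <- paste0(substr(out, 1L, p), v$alt[i],
                  substr(out, p + nchar(v$ref[i]) + 1L, nchar(out)))
  }
  out
}

## Global alignment of a haplotype against a reference with the package's
## scoring contract: match +1, mismatch -1, gap open -2, gap extend -1.
align_global <- function(haplotype, reference) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(haplotype),
    subject = Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1
  )
}

#' Derive normalized variants from a haplotype/reference alignment
#'
#' Globally aligns the haplotype to the reference (match +1 / mismatch -1 /
#' gap open -2 / extend -1), walks the alignment columns, and emits SNVs and
#' indels in left-aligned parsimonious form with 0-based positions.
#'
#' @param haplotype,reference DNA strings.
#' @return A list with `variants` (data frame), `score` (alignment score) and
#'   `alignment` (the `PairwiseAlignments` object).
#' @export
derive_variants <- function(haplotype, reference) {
  aln <- align_global(haplotype, reference)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  stopifnot(length(p) == length(s))
  out <- list()
  ref_pos <- 0L  # 0-based position of the next reference base
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (s[i] != "-" && p[i] != "-") {
      if (s[i] != p[i]) {
        out[[length(out) + 1L]] <- normalize_variant(ref_pos, s[i], p[i], reference)
      }
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    } else if (s[i] == "-") {            # insertion relative to reference
      j <- i
      while (j <= n && s[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- normalize_variant(
        ref_pos, "", paste(p[i:(j - 1L)], collapse = ""), reference)
      i <- j
    } else {                             # deletion relative to reference
      j <- i
      while (j <= n && p[j] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- normalize_variant(
        ref_pos, paste(s[i:(j - 1L)], collapse = ""), "", reference)
      ref_pos <- ref_pos + (j - i)
      i <- j
    }
  }
  v <- if (length(out)) do.call(rbind, out) else variant_frame()
  v <- v[order(v$pos, v$ref, v$alt), , drop = FALSE]
  rownames(v) <- NULL
  list(variants = v, score = Biostrings::score(aln), alignment = aln)
}
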
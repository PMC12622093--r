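#' Synthetic CYP2D6/CYP2D7/spacer reference surrogates
#'
#' Builds a labeled reference set for paralog painting: a random D6 gene
#' surrogate, a D7 surrogate derived from it by i.i.d. per-base substitution
#' at the stated divergence (default 0.05, mirroring the ~94% real
#' CYP2D6/CYP2D7 identity), and an independent spacer sequence. Both gene
#' surrogates have the same length so hybrid breakpoint fractions line up
#' between the paralogs.
#'
#' @param gene_length Length of each gene surrogate in bp.
#' @param spacer_length Length of the intergenic spacer surrogate.
#' @param divergence Per-base substitution rate between D6 and D7.
#' @param seed Integer seed; the set is a pure function of its arguments.
#' @return Object of class `gene_reference_set`: named list of sequences
#'   `D6`, `D7`, `SPACER` with the divergence recorded as an attribute.
#' @export
synthetic_cyp_refs <- function(gene_length = 1500L, spacer_length = 600L,
                               divergence = 0.05, seed = 20260927L) {
  withr::with_seed(seed, {
    d6 <- random_dna(gene_length)
    d7 <- mutate_sequence(d6, divergence)
    sp <- random_dna(spacer_length)
    refs <- structure(list(D6 = d6, D7 = d7, SPACER = sp),
                      class = "gene_reference_set")
    attr(refs, "divergence") <- divergence
    if (divergence == 0) {
      warning("divergence 0: paralog painting will be ambiguous")
    }
    refs
  })
}

#' Specify a synthetic CYP2D6-CYP2D7 locus structure
#'
#' The structure is an ordered list of segment descriptors: the strings
#' `"D6"`, `"D7"`, `"SPACER"`, or a hybrid descriptor
#' `list(gene5 = , gene3 = , breakpoint_fraction = )` with the breakpoint
#' fraction strictly inside (0, 1).
#'
#' @param structure Non-empty list (or character vector) of segment
#'   descriptors.
#' @param seed Integer seed recorded with the spec.
#' @return Object of class `cyp_config_spec`.
#' @export
cyp_config_spec <- function(structure, seed = 1L) {
  if (length(structure) == 0) stop("structure must be non-empty")
  structure <- lapply(structure, function(s) {
    if (is.character(s)) {
      if (!s %in% c("D6", "D7", "SPACER")) stop("unknown segment label: ", s)
      return(s)
    }
    stopifnot(is.list(s), all(c("gene5", "gene3", "breakpoint_fraction") %in% names(s)))
    if (s$breakpoint_fraction <= 0 || s$breakpoint_fraction >= 1) {
      stop("breakpoint_fraction must be strictly inside (0, 1)")
    }
    if (!s$gene5 %in% c("D6", "D7") || !s$gene3 %in% c("D6", "D7")) {
      stop("hybrid genes must be D6 or D7")
    }
    s
  })
  structure(list(structure = structure, seed = as.integer(seed)),
            class = "cyp_config_spec")
}

#' Generate a synthetic CYP locus haplotype with structural truth
#'
#' Concatenates reference segments per the spec's structure. Hybrid segments
#' take the 5' gene up to `round(f * gene_length)` and switch to the 3' gene
#' at the same fraction of its length, emulating gene-conversion fusion
#' alleles. The truth records each gene copy (label, haplotype offsets,
#' breakpoint offset for hybrids), per-gene copy numbers, and the
#' configuration class/notation by construction.
#'
#' @param spec A [cyp_config_spec()].
#' @param refs A [synthetic_cyp_refs()] reference set.
#' @param noise_rate Optional i.i.d. per-base substitution rate applied to
#'   the finished haplotype (default 0: clean consensus sequences). Seeded by
#'   the spec's seed.
#' @return List with `haplotype` (DNA string) and `truth` (a
#'   `structural_configuration`, same shape as [segment_structure()] output).
#' @export
gen_cyp_locus <- function(spec, refs, noise_rate = 0) {
  stopifnot(inherits(spec, "cyp_config_spec"), inherits(refs, "gene_reference_set"))
  pieces <- character(0)
  copies <- list()
  offset <- 0L
  for (seg in spec$structure) {
    if (is.character(seg)) {
      s <- refs[[seg]]
      if (seg != "SPACER") {
        copies[[length(copies) + 1L]] <- data.frame(
          label = seg, start = offset, end = offset + nchar(s),
          breakpoint = NA_integer_, stringsAsFactors = FALSE)
      }
    } else {
      g5 <- refs[[seg$gene5]]; g3 <- refs[[seg$gene3]]
      b5 <- as.integer(round(seg$breakpoint_fraction * nchar(g5)))
      b3 <- as.integer(round(seg$breakpoint_fraction * nchar(g3)))
      s <- paste0(substr(g5, 1L, b5), substr(g3, b3 + 1L, nchar(g3)))
      copies[[length(copies) + 1L]] <- data.frame(
        label = paste0(seg$gene5, "::", seg$gene3),
        start = offset, end = offset + nchar(s),
        breakpoint = offset + b5, stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, s)
    offset <- offset + nchar(s)
  }
  copies <- do.call(rbind, copies)
  truth <- structure(list(
    copies = copies,
    copy_number = count_copies(copies$label),
    configuration_class = configuration_class(copies$label)
  ), class = "structural_configuration")
  truth$notation <- classify_configuration(truth)
  haplotype <- paste(pieces, collapse = "")
  if (noise_rate > 0) {
    haplotype <- withr::with_seed(spec$seed,
                                  mutate_sequence(haplotype, noise_rate))
  }
  list(haplotype = haplotype, truth = truth)
}
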
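## Synthetic pharmacogene surrogate and packaged allele definitions.
##
## Real PharmVar definition sequences are not redistributed here; instead a
## seeded synthetic gene surrogate carries a small definition set with the
## same shape (core alleles, one suballele, defining variants by position).
## Activity values for the packaged star names are the CPIC-derived defaults.

# deterministic transversion used when picking alt alleles for definitions
.flip_base <- c(A = "C", C = "A", G = "T", T = "G")

#' Synthetic pharmacogene reference with exon annotation
#'
#' A fixed, seeded ~2.4 kb gene surrogate: three exons whose concatenation is
#' a valid CDS (ATG start, no internal stops, terminal stop), separated by
#' random introns and flanks. Used as the gene reference for star-allele
#' calling and translation in examples and tests; it is synthetic and does
#' not reproduce any real CYP2D6 sequence.
#'
#' @return List: `sequence` (DNA string), `exons` (data frame of 0-based
#'   half-open `start`/`end`), `strand` (`"+"`), `protein` (reference amino
#'   acid string, without the terminal stop).
#' @export
synthetic_pgx_reference <- function() {
  withr::with_seed(77190224L, {
    codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                    paste, collapse = "")
    sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
    cds <- paste0("ATG", paste(sample(sense, 331L, replace = TRUE), collapse = ""),
                  "TAA")                     # 333 codons, 999 nt
    exon_len <- c(300L, 399L, 300L)
    stopifnot(sum(exon_len) == nchar(cds))
    parts <- substring(cds, cumsum(c(1L, head(exon_len, -1L))),
                       cumsum(exon_len))
    flank5 <- random_dna(200L); intron1 <- random_dna(250L)
    intron2 <- random_dna(250L); flank3 <- random_dna(200L)
    sequence <- paste0(flank5, parts[1], intron1, parts[2], intron2,
                       parts[3], flank3)
    starts <- c(200L, 200L + exon_len[1] + 250L,
                200L + exon_len[1] + 250L + exon_len[2] + 250L)
    exons <- data.frame(start = starts, end = starts + exon_len)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    list(sequence = sequence, exons = exons, strand = "+",
         protein = sub("\\*$", "", prot))
  })
}

#' Construct a star-allele definition
#'
#' @param star Star name including suballele if any (e.g. `"*4"`, `"*4.013"`).
#' @param variants Variant data frame (`pos` 0-based, `ref`, `alt`), sorted
#'   and non-overlapping; zero rows define the reference allele.
#' @param core Core star name the (sub)allele aggregates to for activity
#'   scoring; defaults to the part before the suballele dot.
#' @return Object of class `allele_definition`.
#' @export
allele_definition <- function(star, variants = variant_frame(), core = NULL) {
  if (nrow(variants) > 0) {
    variants <- variants[order(variants$pos), , drop = FALSE]
    if (anyDuplicated(variants$pos)) stop("defining variants must not overlap")
    ends <- variants$pos + pmax(nchar(variants$ref), 1L)
    if (nrow(variants) > 1 && any(variants$pos[-1] < ends[-nrow(variants)])) {
      stop("defining variants must not overlap")
    }
  }
  rownames(variants) <- NULL
  structure(list(star = star,
                 core = core %||% sub("\\..*$", "", star),
                 variants = variants),
            class = "allele_definition")
}

#' Packaged synthetic star-allele definitions
#'
#' A small definition set on the [synthetic_pgx_reference()] surrogate,
#' mirroring the shape of PharmVar-style tables: a reference allele (*1)
#' defined by zero variants, no-function alleles (*4 with a suballele
#' *4.013 adding one extra variant), and decreased-function alleles
#' (*10, *17, *41). Positions are synthetic; ref alleles are read off the
#' surrogate so definitions are always internally consistent.
#'
#' @param reference Output of [synthetic_pgx_reference()].
#' @return Named list of [allele_definition()] objects.
#' @export
star_allele_definitions <- function(reference = synthetic_pgx_reference()) {
  seqs <- reference$sequence
  snv <- function(pos) {
    ref <- substr(seqs, pos + 1L, pos + 1L)
    variant_frame(pos, ref, unname(.flip_base[ref]))
  }
  defs <- list(
    allele_definition("*1"),
    allele_definition("*2",  rbind(snv(120L), snv(1210L))),   # flank + intron
    allele_definition("*4",  rbind(snv(505L), snv(620L))),    # splice region + intron
    allele_definition("*4.013", rbind(snv(505L), snv(620L), snv(1100L)),
                      core = "*4"),
    allele_definition("*10", snv(309L)),                      # exon 1 missense
    allele_definition("*17", snv(850L)),                      # exon 2 missense
    allele_definition("*41", snv(700L))                       # intronic
  )
  names(defs) <- vapply(defs, `[[`, character(1), "star")
  defs
}

#' Star-allele activity table with CPIC-style phenotype bins
#'
#' Reads the packaged activity values (CPIC-derived defaults for the packaged
#' star names) and attaches the phenotype bins used for metabolizer calls:
#' activity score 0 = poor (PM); (0, 1] = intermediate (IM); (1, 2.25] =
#' normal (NM); > 2.25 = ultrarapid (UM). The bins partition `[0, Inf)`.
#'
#' @param path Optional path to a TSV with columns `star`, `activity`
#'   overriding the packaged table.
#' @return Named numeric vector of activity values with a `bins` attribute
#'   (data frame: phenotype, min, max, min_inclusive).
#' @export
activity_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "star_activity.tsv",
                                package = "locuskit", mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
  stopifnot(all(c("star", "activity") %in% names(tab)))
  act <- setNames(tab$activity, tab$star)
  attr(act, "bins") <- data.frame(
    phenotype = c("PM", "IM", "NM", "UM"),
    min = c(0, 0, 1, 2.25), max = c(0, 1, 2.25, Inf),
    min_inclusive = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  act
}
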
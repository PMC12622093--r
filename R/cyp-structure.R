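#' Tile a haplotype into fixed-size windows
#'
#' Consecutive non-overlapping windows of `tile_size` bp; a final remainder
#' shorter than one tile is dropped and counted.
#'
#' @param haplotype DNA string, at least `tile_size` long.
#' @param tile_size Window size in bp (default 100).
#' @return List: `tiles` (character vector), `offsets` (0-based start of each
#'   tile), `tile_size`, `remainder` (dropped 3' bases).
#' @export
tile_haplotype <- function(haplotype, tile_size = 100L) {
  assert_dna(haplotype, "haplotype")
  tile_size <- as.integer(tile_size)
  n <- nchar(haplotype)
  if (n < tile_size) stop("haplotype shorter than one tile")
  k <- n %/% tile_size
  offsets <- (seq_len(k) - 1L) * tile_size
  tiles <- substring(haplotype, offsets + 1L, offsets + tile_size)
  list(tiles = tiles, offsets = offsets, tile_size = tile_size,
       remainder = n - k * tile_size)
}

#' Paint tiles by best-matching reference gene
#'
#' Aligns every tile locally (match +1 / mismatch -1 / gap open -2 /
#' extend -1) against each labeled reference; the tile takes the label of the
#' highest-scoring reference. A MAPQ-like confidence proxy is derived from the
#' best-vs-second-best score gap, `min(60, 2 * gap)`. Tiles whose gap is below
#' `min_score_margin` are labeled `AMBIGUOUS`; tiles whose best score is below
#' `score_floor` are `UNALIGNED`.
#'
#' @param tiles Output of [tile_haplotype()] (or a plain character vector).
#' @param refs A `gene_reference_set` (see [synthetic_cyp_refs()]), or any
#'   named list of reference sequences.
#' @param min_score_margin Minimum best-vs-second-best score gap for an
#'   unambiguous label. The default 2 corresponds to a single discriminating
#'   base under the unit match/mismatch costs.
#' @param score_floor Minimum best score for a tile to count as aligned.
#' @return Object of class `tile_painting`: a data frame with `tile_index`
#'   (0-based), `haplotype_offset`, `label`, `score`, `margin`, `mapq_proxy`,
#'   `ref_coordinate` (0-based start of the best local hit in its reference).
#' @export
paint_tiles <- function(tiles, refs, min_score_margin = 2, score_floor = 40) {
  if (is.character(tiles)) {
    tiles <- list(tiles = tiles,
                  offsets = (seq_along(tiles) - 1L) * nchar(tiles[1]),
                  tile_size = nchar(tiles[1]), remainder = 0L)
  }
  labels <- names(refs)
  stopifnot(length(labels) >= 2, !anyDuplicated(labels))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  tset <- Biostrings::DNAStringSet(tiles$tiles)
  scores <- matrix(NA_real_, nrow = length(tiles$tiles), ncol = length(labels),
                   dimnames = list(NULL, labels))
  starts <- scores
  for (lab in labels) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = tset, subject = Biostrings::DNAString(refs[[lab]]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    scores[, lab] <- Biostrings::score(aln)
    starts[, lab] <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
  }
  ord <- t(apply(scores, 1L, order, decreasing = TRUE))
  best <- scores[cbind(seq_len(nrow(scores)), ord[, 1L])]
  second <- scores[cbind(seq_len(nrow(scores)), ord[, 2L])]
  margin <- best - second
  label <- labels[ord[, 1L]]
  label[margin < min_score_margin] <- "AMBIGUOUS"
  label[best < score_floor] <- "UNALIGNED"
  out <- data.frame(
    tile_index = seq_along(tiles$tiles) - 1L,
    haplotype_offset = tiles$offsets,
    label = label,
    score = best,
    margin = margin,
    mapq_proxy = pmin(60, 2 * pmax(margin, 0)),
    ref_coordinate = starts[cbind(seq_len(nrow(starts)), ord[, 1L])],
    stringsAsFactors = FALSE)
  attr(out, "tile_size") <- tiles$tile_size
  attr(out, "remainder") <- tiles$remainder
  class(out) <- c("tile_painting", "data.frame")
  out
}

## Per-gene copy counts; hybrids are tallied separately, contributing to
## neither pure-gene copy number.
count_copies <- function(labels) {
  c(D6 = sum(labels == "D6"), D7 = sum(labels == "D7"),
    hybrid = sum(grepl("::", labels, fixed = TRUE)))
}

configuration_class <- function(labels) {
  cn <- count_copies(labels)
  if (cn["hybrid"] > 0) return("hybrid")
  if (cn["D6"] == 0) return("deletion")
  if (cn["D6"] >= 2) return("duplication")
  if (cn["D6"] == 1 && cn["D7"] == 1) return("canonical")
  "other"
}

#' Segment a tile painting into a structural configuration
#'
#' Run-length encodes the tile labels (absorbing runs shorter than
#' `min_run_tiles`, which suppresses single-tile label flicker from paralog
#' homology), then merges consecutive gene-label runs between spacer runs
#' into gene copies. A copy whose tiles switch label mid-body, with at least
#' `min_run_tiles` support on both sides, becomes a hybrid `X::Y` with the
#' breakpoint placed at the first tile of the new label (resolution is
#' inherently one tile).
#'
#' @param painting A `tile_painting` from [paint_tiles()].
#' @param min_run_tiles Minimum run length, in tiles, for a label run to be
#'   believed (default 3, i.e. 300 bp at the default tile size).
#' @return Object of class `structural_configuration`: `copies` (data frame
#'   with `label`, `start`/`end` haplotype offsets, `start_tile`/`end_tile`,
#'   `breakpoint` offset or NA), `copy_number` (named D6/D7/hybrid counts),
#'   `configuration_class`, and `notation` (see [classify_configuration()]).
#' @export
segment_structure <- function(painting, min_run_tiles = 3L) {
  stopifnot(nrow(painting) > 0)
  tile_size <- attr(painting, "tile_size") %||% 100L
  labels <- painting$label
  if (all(labels %in% c("AMBIGUOUS", "UNALIGNED"))) {
    warning("all tiles ambiguous or unaligned; configuration class 'other'")
    out <- structure(list(
      copies = data.frame(label = character(), start = integer(),
                          end = integer(), start_tile = integer(),
                          end_tile = integer(), breakpoint = integer(),
                          stringsAsFactors = FALSE),
      copy_number = c(D6 = 0L, D7 = 0L, hybrid = 0L),
      configuration_class = "other"), class = "structural_configuration")
    out$notation <- ""
    return(out)
  }
  # absorb short runs (of any label) into their neighbors
  r <- rle(labels)
  keep <- r$lengths >= min_run_tiles
  if (!any(keep)) keep[which.max(r$lengths)] <- TRUE
  vals <- r$values
  vals[!keep] <- NA_character_
  expanded <- rep(vals, r$lengths)
  # fill NA from the previous believed label, then from the next
  filled <- expanded
  for (i in seq_along(filled)) {
    if (is.na(filled[i]) && i > 1L) filled[i] <- filled[i - 1L]
  }
  for (i in rev(seq_along(filled))) {
    if (is.na(filled[i]) && i < length(filled)) filled[i] <- filled[i + 1L]
  }
  r2 <- rle(filled)
  # group gene runs into copies: consecutive D6/D7 runs with no intervening
  # spacer/ambiguous run belong to one copy
  all_runs <- data.frame(label = r2$values,
                         start_tile = cumsum(c(0L, head(r2$lengths, -1L))),
                         n_tiles = r2$lengths, stringsAsFactors = FALSE)
  is_gene <- all_runs$label %in% c("D6", "D7")
  copy_id <- cumsum(!is_gene)  # increments at every non-gene run
  copies <- list()
  for (grp in split(all_runs[is_gene, , drop = FALSE], copy_id[is_gene])) {
    if (nrow(grp) == 0) next
    start_tile <- grp$start_tile[1]
    end_tile <- grp$start_tile[nrow(grp)] + grp$n_tiles[nrow(grp)]
    if (length(unique(grp$label)) == 1L) {
      lab <- grp$label[1]
      bp <- NA_integer_
    } else {
      # hybrid: label switches mid-copy; breakpoint at the first tile of the
      # final label's run
      lab <- paste0(grp$label[1], "::", grp$label[nrow(grp)])
      switch_run <- max(which(grp$label != grp$label[nrow(grp)])) + 1L
      bp <- grp$start_tile[switch_run] * tile_size
    }
    copies[[length(copies) + 1L]] <- data.frame(
      label = lab, start = start_tile * tile_size, end = end_tile * tile_size,
      start_tile = start_tile, end_tile = end_tile, breakpoint = bp,
      stringsAsFactors = FALSE)
  }
  copies <- if (length(copies)) do.call(rbind, copies) else
    data.frame(label = character(), start = integer(), end = integer(),
               start_tile = integer(), end_tile = integer(),
               breakpoint = integer(), stringsAsFactors = FALSE)
  out <- structure(list(
    copies = copies,
    copy_number = count_copies(copies$label),
    configuration_class = configuration_class(copies$label)
  ), class = "structural_configuration")
  out$notation <- classify_configuration(out)
  out
}

#' Canonical notation for a structural configuration
#'
#' Joins the ordered gene copies with `-`, writing hybrids in fusion notation
#' (`CYP2D6::7`, `CYP2D7::6`): e.g. the canonical single-copy arrangement is
#' `CYP2D6-CYP2D7`, a D7::D6 conversion allele upstream of an intact D7 is
#' `CYP2D7::6-CYP2D7`. A configuration with no CYP2D6 copy is the full-gene
#' deletion class.
#'
#' @param config A `structural_configuration`.
#' @return The notation string.
#' @export
classify_configuration <- function(config) {
  stopifnot(inherits(config, "structural_configuration"))
  lab <- vapply(config$copies$label, function(l) {
    switch(l,
           "D6" = "CYP2D6", "D7" = "CYP2D7",
           "D6::D7" = "CYP2D6::7", "D7::D6" = "CYP2D7::6",
           l)
  }, character(1))
  paste(lab, collapse = "-")
}
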
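#' Packaged repeat-classification rule set
#'
#' Clinical repeat-count boundaries, in repeat units, for the packaged
#' disease loci:
#' \itemize{
#'   \item FMR1 (5' UTR CGG): normal < 55; premutation 55-200; full mutation
#'     > 200. Unit counts include AGG interruption units.
#'   \item HTT (coding CAG): normal < 27; intermediate 27-35;
#'     reduced-penetrance >= 36. Counts refer to the pure CAG tract (plus any
#'     internal interruptions), excluding the downstream CAA-CAG/CCG cassette,
#'     matching the clinical CAG-count convention those boundaries assume.
#'   \item ATXN3 (coding CAG): pathogenic (high penetrance) > 55.
#' }
#' FMR1 instability tiers on the uninterrupted 3' CGG run: moderate 25-33,
#' high >= 34.
#'
#' @return A list of per-gene boundary tables plus the FMR1 tier boundaries
#'   and per-gene canonical interruption sets.
#' @export
repeat_rules <- function() {
  list(
    genes = list(
      FMR1 = data.frame(
        category = c("normal", "premutation", "full_mutation"),
        min = c(0L, 55L, 201L), max = c(54L, 200L, Inf),
        stringsAsFactors = FALSE),
      HTT = data.frame(
        category = c("normal", "intermediate", "reduced_penetrance"),
        min = c(0L, 27L, 36L), max = c(26L, 35L, Inf),
        stringsAsFactors = FALSE),
      ATXN3 = data.frame(
        category = c("normal", "pathogenic"),
        min = c(0L, 56L), max = c(55L, Inf),
        stringsAsFactors = FALSE)
    ),
    fmr1_tiers = data.frame(
      tier = c("none", "moderate", "high"),
      min = c(0L, 25L, 34L), max = c(24L, 33L, Inf),
      stringsAsFactors = FALSE),
    canonical_interruptions = list(FMR1 = "AGG", HTT = c("CAA", "CAG"))
  )
}

#' Decompose a repeat sequence into motif-length units
#'
#' Windows the sequence into consecutive non-overlapping motif-length units.
#' When the sequence length is not a multiple of the motif length, the
#' register (0-based start offset in `0..len(motif)-1`) maximizing the number
#' of exact motif units is chosen; ties go to the smallest offset. Any leading
#' offset and trailing remainder shorter than one motif are dropped and
#' recorded.
#'
#' @param sequence Repeat-region DNA string (flanks already stripped).
#' @param motif Repeat motif.
#' @return A list of class `unit_decomposition`: `units` (character vector),
#'   `offset` (dropped 5' bases), `remainder` (dropped 3' bases), `consumed`
#'   (the windowed subsequence), and `empty` flag (sequence shorter than one
#'   motif).
#' @export
decompose_units <- function(sequence, motif) {
  assert_dna(motif, "motif")
  if (nchar(sequence) > 0) assert_dna(sequence, "sequence")
  k <- nchar(motif)
  n <- nchar(sequence)
  if (n < k) {
    return(structure(list(units = character(), offset = 0L,
                          remainder = sequence, consumed = "", empty = TRUE),
                     class = "unit_decomposition"))
  }
  windows_at <- function(off) {
    u <- (n - off) %/% k
    starts <- off + seq(0L, by = k, length.out = u) + 1L
    substring(sequence, starts, starts + k - 1L)
  }
  offsets <- 0:(k - 1L)
  offsets <- offsets[(n - offsets) >= k]
  match_counts <- vapply(offsets, function(off) sum(windows_at(off) == motif),
                         integer(1))
  best <- offsets[which.max(match_counts)]  # which.max takes the first tie
  units <- windows_at(best)
  used <- best + length(units) * k
  structure(list(units = units, offset = best,
                 remainder = if (used < n) substr(sequence, used + 1L, n) else "",
                 consumed = substr(sequence, best + 1L, used),
                 empty = FALSE),
            class = "unit_decomposition")
}

#' Length of the longest purely repeating segment
#'
#' Maximal contiguous run of exact motif copies, in units; 0 for empty input.
#'
#' @param units Unit character vector (or a `unit_decomposition`).
#' @param motif Repeat motif.
#' @return Non-negative integer.
#' @export
longest_pure_run <- function(units, motif) {
  if (inherits(units, "unit_decomposition")) units <- units$units
  if (length(units) == 0) return(0L)
  runs <- rle(units == motif)
  if (!any(runs$values)) return(0L)
  as.integer(max(runs$lengths[runs$values]))
}

#' Detect interruption units within a repeat tract
#'
#' Reports every non-motif unit with its 0-based index and whether it belongs
#' to the locus's canonical interruption set (e.g. AGG within an FMR1 CGG
#' tract; CAA within an HTT CAG tract).
#'
#' @param units Unit character vector (or a `unit_decomposition`).
#' @param motif Repeat motif.
#' @param canonical Character vector of canonical interruption units for the
#'   locus (see [repeat_rules()]`$canonical_interruptions`).
#' @return Data frame with `unit_index` (0-based), `unit`, `canonical`.
#' @export
detect_interruptions <- function(units, motif, canonical = character()) {
  if (inherits(units, "unit_decomposition")) units <- units$units
  hit <- which(units != motif)
  data.frame(unit_index = hit - 1L, unit = units[hit],
             canonical = units[hit] %in% canonical,
             stringsAsFactors = FALSE)
}

#' Characterize one repeat allele
#'
#' Runs the full decomposition: unit windowing, longest pure run, and
#' interruption detection, returning a `repeat_allele` record.
#'
#' @param sequence Repeat-region DNA string.
#' @param motif Repeat motif.
#' @param locus_id,haplotype_id Identifiers carried through to the record.
#' @param canonical Canonical interruption set for the locus.
#' @return An object of class `repeat_allele` with fields `units`,
#'   `total_units`, `longest_pure_run`, `interruptions` (with canonical flag),
#'   `offset`, `remainder`.
#' @export
characterize_allele <- function(sequence, motif, locus_id = NA_character_,
                                haplotype_id = NA_character_,
                                canonical = character()) {
  dec <- decompose_units(sequence, motif)
  ints <- detect_interruptions(dec, motif, canonical)
  structure(list(
    locus_id = locus_id, haplotype_id = haplotype_id,
    sequence = dec$consumed, motif = motif, units = dec$units,
    total_units = length(dec$units),
    longest_pure_run = longest_pure_run(dec, motif),
    interruptions = ints, offset = dec$offset, remainder = dec$remainder
  ), class = "repeat_allele")
}

#' Classify a repeat allele against clinical repeat-count boundaries
#'
#' Maps a total unit count to exactly one category for the given gene, with
#' boundaries inclusive as printed (e.g. FMR1 55 units is premutation, HTT 36
#' is reduced-penetrance, ATXN3 is pathogenic only strictly above 55). FMR1
#' counts include AGG interruption units.
#'
#' @param gene Gene symbol present in `rules` ("FMR1", "HTT", "ATXN3").
#' @param allele A `repeat_allele` or a plain unit count.
#' @param rules Rule set from [repeat_rules()].
#' @return A single category label string.
#' @export
classify_allele <- function(gene, allele, rules = repeat_rules()) {
  if (!gene %in% names(rules$genes)) stop("unknown gene: ", gene)
  n <- if (inherits(allele, "repeat_allele")) allele$total_units else as.integer(allele)
  if (is.na(n) || n < 0) stop("allele unit count must be a non-negative integer")
  tab <- rules$genes[[gene]]
  hit <- which(n >= tab$min & n <= tab$max)
  stopifnot(length(hit) == 1L)
  tab$category[hit]
}

#' FMR1 instability tier from the uninterrupted 3' CGG run
#'
#' Loss of the 3' AGG interruption lengthens the pure CGG run at the distal
#' end of the tract, the segment most prone to expansion on transmission. The
#' tier is determined by the run of exact motif units at the 3' end (distal to
#' the last interruption, or the whole tract if uninterrupted): 25-33 units is
#' the moderate tier, >= 34 the high tier.
#'
#' @param allele A `repeat_allele` (or a plain 3' pure-run length).
#' @param rules Rule set from [repeat_rules()].
#' @return One of `"none"`, `"moderate"`, `"high"`.
#' @export
fmr1_instability_tier <- function(allele, rules = repeat_rules()) {
  run <- if (inherits(allele, "repeat_allele")) {
    u <- allele$units
    if (length(u) == 0) 0L else {
      r <- rle(u == allele$motif)
      if (r$values[length(r$values)]) r$lengths[length(r$lengths)] else 0L
    }
  } else as.integer(allele)
  tab <- rules$fmr1_tiers
  tab$tier[which(run >= tab$min & run <= tab$max)]
}

#' Per-locus repeat variability statistics
#'
#' For each locus: the median absolute deviation of allele length (in repeat
#' units, unscaled: `median(|x - median(x)|)`) and the 50th/99th percentiles
#' of the longest pure run. Quantiles use linear interpolation between order
#' statistics (type 7); the convention is recorded in the output attributes.
#' By default the MAD is computed over total allele length (`n_units`);
#' set `mad_on = "pure"` to use the pure-segment length instead.
#'
#' @param alleles Data frame with columns `locus_id`, `n_units`,
#'   `longest_pure_run` (one row per allele), e.g. from [gen_repeat_cohort()]
#'   or [characterize_allele()] results stacked.
#' @param mad_on `"total"` (default) or `"pure"`.
#' @return Data frame: `locus_id`, `n_alleles`, `length_mad`, `median_pure`,
#'   `p99_pure`, `undefined` (TRUE when fewer than 2 alleles).
#' @export
locus_variability <- function(alleles, mad_on = c("total", "pure")) {
  mad_on <- match.arg(mad_on)
  stopifnot(all(c("locus_id", "n_units", "longest_pure_run") %in% names(alleles)))
  out <- lapply(split(alleles, alleles$locus_id), function(a) {
    n <- nrow(a)
    if (n < 2) {
      return(data.frame(locus_id = a$locus_id[1], n_alleles = n,
                        length_mad = NA_real_, median_pure = NA_real_,
                        p99_pure = NA_real_, undefined = TRUE,
                        stringsAsFactors = FALSE))
    }
    len <- if (mad_on == "total") a$n_units else a$longest_pure_run
    q <- quantile(a$longest_pure_run, c(0.5, 0.99), type = 7, names = FALSE)
    data.frame(locus_id = a$locus_id[1], n_alleles = n,
               length_mad = median(abs(len - median(len))),
               median_pure = q[1], p99_pure = q[2], undefined = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "quantile_type") <- 7L
  attr(res, "mad_on") <- mad_on
  res
}

#' Nominate candidate unstable repeat loci
#'
#' A locus is flagged as a candidate when it is not a known pathogenic locus
#' and its excess length statistic (99th percentile minus median of the
#' longest pure run) is at least the minimum excess observed over the known
#' pathogenic loci present in the table. Known pathogenic loci occupy the
#' right tail of this statistic, so the minimum over them is the least
#' stringent cut that still separates every known locus.
#'
#' @param variability Output of [locus_variability()].
#' @param known_pathogenic_ids Character vector of known pathogenic locus ids;
#'   at least one must be present in the table.
#' @return Data frame of candidate loci (`locus_id`, `excess`) with the
#'   threshold in the `threshold` attribute.
#' @export
flag_candidates <- function(variability, known_pathogenic_ids) {
  v <- variability[!variability$undefined, , drop = FALSE]
  v$excess <- v$p99_pure - v$median_pure
  known <- v[v$locus_id %in% known_pathogenic_ids, , drop = FALSE]
  if (nrow(known) == 0) {
    stop("no known pathogenic loci present in the table; threshold undefined")
  }
  thr <- min(known$excess)
  cand <- v[!(v$locus_id %in% known_pathogenic_ids) & v$excess >= thr,
            c("locus_id", "excess"), drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "threshold") <- thr
  cand
}
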
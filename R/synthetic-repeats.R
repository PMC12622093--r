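#' Specify a synthetic tandem-repeat allele
#'
#' A `repeat_spec` describes one haplotype's repeat allele as a motif, a unit
#' count, and a schedule of interruptions: unit indices (0-based) whose motif
#' copy is replaced by a different, equal-length triplet (e.g. AGG inside an
#' FMR1 CGG tract). Flanks default to fixed 200 bp seeded sequences that are
#' guaranteed motif-free so the repeat boundary is unambiguous.
#'
#' @param locus_id Locus identifier string.
#' @param motif Repeat motif over {A,C,G,T}, 1-6 bp.
#' @param n_units Number of repeat units (positive integer).
#' @param interruptions Data frame with columns `unit_index` (0-based, strictly
#'   increasing, `< n_units`) and `motif` (interruption unit, same length as
#'   the repeat motif), or `NULL` for a pure allele.
#' @param flank5,flank3 Flanking sequences; `NULL` uses seeded motif-free
#'   defaults of `flank_length` bp.
#' @param flank_length Length of the default flanks.
#' @param seed Seed used only to draw the default flanks.
#' @return An object of class `repeat_spec`.
#' @export
repeat_spec <- function(locus_id, motif, n_units, interruptions = NULL,
                        flank5 = NULL, flank3 = NULL, flank_length = 200L,
                        seed = 1L) {
  assert_dna(motif, "motif")
  if (nchar(motif) < 1 || nchar(motif) > 6) stop("motif must be 1-6 bp")
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1) stop("n_units must be a positive integer")
  if (!is.null(interruptions) && nrow(interruptions) > 0) {
    idx <- as.integer(interruptions$unit_index)
    if (any(diff(idx) <= 0) || any(idx < 0) || any(idx >= n_units)) {
      stop("interruption indices must be strictly increasing and < n_units")
    }
    for (m in interruptions$motif) {
      assert_dna(m, "interruption motif")
      if (nchar(m) != nchar(motif)) {
        stop("interruption motif length must equal repeat motif length")
      }
    }
    interruptions <- data.frame(unit_index = idx,
                                motif = as.character(interruptions$motif),
                                stringsAsFactors = FALSE)
  } else {
    interruptions <- data.frame(unit_index = integer(), motif = character(),
                                stringsAsFactors = FALSE)
  }
  if (is.null(flank5) || is.null(flank3)) {
    flanks <- withr::with_seed(seed, list(
      f5 = random_dna_avoiding(flank_length, motif),
      f3 = random_dna_avoiding(flank_length, motif)
    ))
    flank5 <- flank5 %||% flanks$f5
    flank3 <- flank3 %||% flanks$f3
  }
  assert_dna(flank5, "flank5"); assert_dna(flank3, "flank3")
  structure(list(locus_id = as.character(locus_id), motif = motif,
                 n_units = n_units, interruptions = interruptions,
                 flank5 = flank5, flank3 = flank3),
            class = "repeat_spec")
}

#' Generate one repeat allele with ground truth
#'
#' Builds `flank5 + units + flank3` where the units are `n_units` motif copies
#' with the scheduled interruption units substituted, and returns the truth
#' annotation (unit list, longest pure run, interruption positions) alongside
#' the sequence.
#'
#' @param spec A [repeat_spec()].
#' @return A list with `sequence` (full flanked sequence), `repeat_sequence`
#'   (repeat region only), and `truth` (a `repeat_allele` as produced by
#'   [characterize_allele()], computed directly from the construction).
#' @export
gen_repeat_allele <- function(spec) {
  stopifnot(inherits(spec, "repeat_spec"))
  units <- rep(spec$motif, spec$n_units)
  if (nrow(spec$interruptions) > 0) {
    units[spec$interruptions$unit_index + 1L] <- spec$interruptions$motif
  }
  repeat_seq <- paste(units, collapse = "")
  is_pure <- units == spec$motif
  runs <- rle(is_pure)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  truth <- structure(list(
    locus_id = spec$locus_id, haplotype_id = NA_character_,
    sequence = repeat_seq, motif = spec$motif, units = units,
    total_units = length(units), longest_pure_run = as.integer(longest),
    interruptions = data.frame(unit_index = which(!is_pure) - 1L,
                               unit = units[!is_pure], stringsAsFactors = FALSE),
    offset = 0L, remainder = ""
  ), class = "repeat_allele")
  list(sequence = paste0(spec$flank5, repeat_seq, spec$flank3),
       repeat_sequence = repeat_seq,
       truth = truth)
}

#' Generate a seeded multi-locus repeat cohort
#'
#' Draws per-haplotype unit counts for each catalog template from a log-normal
#' length model `round(median * exp(N(0, dispersion)))` (dispersion 0 puts
#' every allele exactly at the median), optionally with a planted heavy right
#' tail, and installs periodic interruptions where the template asks for them.
#'
#' @param catalog A list of templates; each template is a list with fields
#'   `locus_id`, `motif`, `median`, and optionally `dispersion` (default
#'   taken from `dispersion` argument), `tail_prob`/`tail_factor` (heavy-tail
#'   planting: with probability `tail_prob` the drawn length is multiplied by
#'   `tail_factor`; defaults 0/1), `interruption_period` and
#'   `interruption_motif` (an interruption every `period` units; default none).
#' @param n_haplotypes Number of haplotypes per locus (>= 2).
#' @param dispersion Default log-scale dispersion for templates without one.
#' @param seed Integer seed; the output is a pure function of
#'   `(catalog, n_haplotypes, dispersion, seed)`.
#' @param keep_sequence Keep the repeat sequence column (set `FALSE` to save
#'   memory for large catalogs).
#' @return A list with `alleles` (data frame: locus_id, haplotype_id, motif,
#'   sequence, n_units, longest_pure_run, n_interruptions) carrying the truth
#'   of every generated allele.
#' @export
gen_repeat_cohort <- function(catalog, n_haplotypes, dispersion = 0.05,
                              seed = 1L, keep_sequence = TRUE) {
  if (length(catalog) == 0) stop("catalog must contain at least one template")
  n_haplotypes <- as.integer(n_haplotypes)
  if (n_haplotypes < 2) stop("n_haplotypes must be >= 2")
  withr::with_seed(seed, {
    rows <- lapply(catalog, function(tpl) {
      disp <- tpl$dispersion %||% dispersion
      tail_prob <- tpl$tail_prob %||% 0
      tail_factor <- tpl$tail_factor %||% 1
      n <- pmax(1L, as.integer(round(tpl$median * exp(rnorm(n_haplotypes, 0, disp)))))
      tail_hit <- runif(n_haplotypes) < tail_prob
      n[tail_hit] <- pmax(1L, as.integer(round(n[tail_hit] * tail_factor)))
      per <- tpl$interruption_period %||% NA_integer_
      imotif <- tpl$interruption_motif %||% NA_character_
      sub <- lapply(seq_len(n_haplotypes), function(h) {
        ints <- NULL
        if (!is.na(per) && !is.na(imotif) && n[h] > per) {
          idx <- seq(per, n[h] - 1L, by = per)
          ints <- data.frame(unit_index = idx, motif = imotif,
                             stringsAsFactors = FALSE)
        }
        sp <- repeat_spec(tpl$locus_id, tpl$motif, n[h], ints,
                          flank5 = "", flank3 = "")
        g <- gen_repeat_allele(sp)
        data.frame(locus_id = tpl$locus_id,
                   haplotype_id = sprintf("hap%04d", h),
                   motif = tpl$motif,
                   sequence = if (keep_sequence) g$repeat_sequence else NA_character_,
                   n_units = g$truth$total_units,
                   longest_pure_run = g$truth$longest_pure_run,
                   n_interruptions = nrow(g$truth$interruptions),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, sub)
    })
    alleles <- do.call(rbind, rows)
    rownames(alleles) <- NULL
    list(alleles = alleles)
  })
}
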
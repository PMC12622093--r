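#' Assign a star allele to a haplotype
#'
#' Derives the haplotype's variants from a global alignment to the gene
#' reference (match +1 / mismatch -1 / gap open -2 / extend -1), then scores
#' every definition whose defining variants are ALL present — a definition
#' with any missing defining variant is never assigned. Among candidates the
#' best is chosen by (1) most matched defining variants, (2) highest
#' alignment score of the haplotype against the candidate's allele sequence
#' (the reference with its defining variants applied), (3) fewest extra
#' variants. Exact ties are surfaced via the `ambiguous` flag rather than
#' broken. With no qualifying definition the call is `NO_CALL`.
#'
#' Variant comparison uses left-aligned parsimonious representations, so
#' indel representation differences cannot break the all-variants test.
#'
#' @param haplotype Haplotype DNA string over the gene region.
#' @param reference Gene reference DNA string.
#' @param definitions List of [allele_definition()] objects (non-empty).
#' @param haplotype_id Optional identifier carried into the call.
#' @return Object of class `haplotype_call`: `best_star`, `core_star`,
#'   `score`, `matched_defining`, `missing_defining` (0 whenever a star is
#'   assigned), `novel_variants`, `ambiguous`, `tied`, `variants` (all
#'   haplotype variants).
#' @export
call_star_allele <- function(haplotype, reference, definitions,
                             haplotype_id = NA_character_) {
  if (length(definitions) == 0) stop("empty definition set")
  assert_dna(haplotype, "haplotype")
  drv <- derive_variants(haplotype, reference)
  hap_keys <- variant_key(drv$variants)
  cand <- Filter(function(d) all(variant_key(d$variants) %in% hap_keys),
                 definitions)
  if (length(cand) == 0) {
    return(structure(list(
      haplotype_id = haplotype_id, best_star = "NO_CALL", core_star = "NO_CALL",
      score = drv$score, matched_defining = 0L, missing_defining = NA_integer_,
      novel_variants = drv$variants, ambiguous = FALSE, tied = character(),
      variants = drv$variants), class = "haplotype_call"))
  }
  matched <- vapply(cand, function(d) nrow(d$variants), integer(1))
  scores <- vapply(cand, function(d) {
    allele_seq <- apply_variants(reference, d$variants)
    Biostrings::score(align_global(haplotype, allele_seq))
  }, numeric(1))
  extras <- vapply(cand, function(d) {
    sum(!hap_keys %in% variant_key(d$variants))
  }, integer(1))
  ord <- order(-matched, -scores, extras)
  key <- paste(matched, scores, extras)
  best_i <- ord[1]
  tied <- which(key == key[best_i])
  best <- cand[[best_i]]
  novel <- drv$variants[!hap_keys %in% variant_key(best$variants), , drop = FALSE]
  rownames(novel) <- NULL
  structure(list(
    haplotype_id = haplotype_id, best_star = best$star, core_star = best$core,
    score = unname(scores[best_i]), matched_defining = unname(matched[best_i]),
    missing_defining = 0L, novel_variants = novel,
    ambiguous = length(tied) > 1L,
    tied = vapply(cand[tied], `[[`, character(1), "star"),
    variants = drv$variants), class = "haplotype_call")
}

#' Novel variants relative to the assigned definition
#'
#' Set difference between a haplotype's variants and the defining variants of
#' its best-matching definition, both in normalized (left-aligned,
#' parsimonious) representation.
#'
#' @param haplotype_variants Variant data frame (e.g. `call$variants`).
#' @param definition The assigned [allele_definition()].
#' @return Variant data frame of novel variants.
#' @export
find_novel_variants <- function(haplotype_variants, definition) {
  keys <- variant_key(haplotype_variants)
  out <- haplotype_variants[!keys %in% variant_key(definition$variants), ,
                            drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a haplotype's CDS and report protein changes
#'
#' Projects the exon intervals through a global alignment of the haplotype to
#' the gene reference, concatenates the haplotype bases falling in exons
#' (insertions inside an exon are included), translates with the standard
#' genetic code, and reports amino-acid differences as RefAA-Position-AltAA.
#' A CDS length off the reading frame flags a frameshift; a stop gained
#' before the reference terminus flags a premature stop.
#'
#' @param haplotype Haplotype DNA string.
#' @param reference Gene reference DNA string.
#' @param exons Data frame of 0-based half-open `start`/`end` intervals on the
#'   reference (CDS length must be a multiple of 3 for the reference).
#' @param strand `"+"` or `"-"` (minus-strand CDS is reverse-complemented
#'   before translation).
#' @param reference_protein Reference amino-acid string (no terminal stop).
#' @return List: `changes` (data frame `position` (1-based codon), `ref_aa`,
#'   `alt_aa`, `kind` in missense/nonsense, `label`), `frameshift`,
#'   `premature_stop`, `protein` (translated haplotype protein).
#' @export
translate_and_diff <- function(haplotype, reference, exons, strand = "+",
                               reference_protein) {
  stopifnot(nrow(exons) >= 1)
  if (sum(exons$end - exons$start) %% 3L != 0L) {
    stop("reference CDS length is not a multiple of 3")
  }
  aln <- align_global(haplotype, reference)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  in_exon <- function(pos) any(pos >= exons$start & pos < exons$end)
  cds_chars <- character(0)
  ref_pos <- 0L
  for (i in seq_along(p)) {
    if (s[i] != "-") {
      if (in_exon(ref_pos) && p[i] != "-") cds_chars <- c(cds_chars, p[i])
      ref_pos <- ref_pos + 1L
    } else {
      # insertion: belongs to the CDS if it falls strictly inside an exon
      if (ref_pos > 0L && in_exon(ref_pos - 1L) && in_exon(ref_pos)) {
        cds_chars <- c(cds_chars, p[i])
      }
    }
  }
  cds <- paste(cds_chars, collapse = "")
  if (strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  frameshift <- nchar(cds) %% 3L != 0L
  usable <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
  if (substr(usable, 1L, 3L) != "ATG") {
    warning("start codon absent; translating from interval start")
  }
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(usable),
                                             if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", prot, fixed = TRUE)
  premature_stop <- stop_at > 0 && stop_at <= nchar(reference_protein)
  prot_trim <- if (stop_at > 0) substr(prot, 1L, stop_at - 1L) else prot
  n <- min(nchar(prot_trim), nchar(reference_protein))
  ref_aa <- strsplit(reference_protein, "")[[1]]
  alt_aa <- strsplit(prot_trim, "")[[1]]
  changes <- list()
  if (!frameshift) {
    for (i in seq_len(n)) {
      if (ref_aa[i] != alt_aa[i]) {
        changes[[length(changes) + 1L]] <- data.frame(
          position = i, ref_aa = ref_aa[i], alt_aa = alt_aa[i],
          kind = "missense", label = paste0(ref_aa[i], i, alt_aa[i]),
          stringsAsFactors = FALSE)
      }
    }
    if (premature_stop && stop_at <= nchar(reference_protein)) {
      i <- as.integer(stop_at)
      changes[[length(changes) + 1L]] <- data.frame(
        position = i, ref_aa = ref_aa[i], alt_aa = "*",
        kind = "nonsense", label = paste0(ref_aa[i], i, "*"),
        stringsAsFactors = FALSE)
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(position = integer(), ref_aa = character(),
               alt_aa = character(), kind = character(), label = character(),
               stringsAsFactors = FALSE)
  list(changes = changes, frameshift = frameshift,
       premature_stop = premature_stop, protein = prot_trim)
}

#' Combine two haplotype calls into a diplotype with metabolizer phenotype
#'
#' Sums the CPIC activity values of the two core star alleles and bins the
#' activity score into the metabolizer phenotype (see [activity_table()]).
#' If either call is ambiguous, a `NO_CALL`, or absent from the activity
#' table, the phenotype is `indeterminate` with a reason. Symmetric in its
#' two arguments.
#'
#' @param call_a,call_b `haplotype_call` objects (or plain star-name strings).
#' @param activity Activity table from [activity_table()].
#' @return Object of class `diplotype`: `stars` (sorted pair),
#'   `activity_score`, `phenotype`, `reason`.
#' @export
call_diplotype <- function(call_a, call_b, activity = activity_table()) {
  star_of <- function(x) {
    if (inherits(x, "haplotype_call")) {
      if (x$ambiguous) return(NA_character_)
      x$core_star
    } else as.character(x)
  }
  a <- star_of(call_a); b <- star_of(call_b)
  stars <- sort(c(a, b), na.last = TRUE)
  fail <- function(reason) structure(
    list(stars = stars, activity_score = NA_real_,
         phenotype = "indeterminate", reason = reason), class = "diplotype")
  if (any(is.na(stars))) return(fail("ambiguous haplotype call"))
  if (any(stars == "NO_CALL")) return(fail("haplotype without star assignment"))
  if (!all(stars %in% names(activity))) {
    return(fail(paste("star absent from activity table:",
                      paste(setdiff(stars, names(activity)), collapse = ","))))
  }
  score <- sum(activity[stars])
  bins <- attr(activity, "bins")
  hit <- which((score > bins$min | (bins$min_inclusive & score == bins$min)) &
               score <= bins$max)
  structure(list(stars = stars, activity_score = unname(score),
                 phenotype = bins$phenotype[hit[1]], reason = NA_character_),
            class = "diplotype")
}

#' Majority consensus across caller results
#'
#' Returns the most frequent identical call string provided its count reaches
#' `min_agree`; ties at the maximal count, or no call reaching the minimum,
#' yield `INDETERMINATE`.
#'
#' @param calls Named character vector of per-caller call strings (>= 2
#'   callers, unique names).
#' @param min_agree Minimum agreeing callers (default 2).
#' @return The consensus call string or `"INDETERMINATE"`.
#' @export
consensus_call <- function(calls, min_agree = 2L) {
  if (length(calls) < 2) stop("at least 2 caller inputs required")
  if (!is.null(names(calls)) && anyDuplicated(names(calls))) {
    stop("caller ids must be unique")
  }
  tab <- table(calls)
  top <- max(tab)
  if (top < min_agree || sum(tab == top) > 1L) return("INDETERMINATE")
  names(tab)[which.max(tab)]
}
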
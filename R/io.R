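#' Read a FASTA file into an ordered id/sequence table
#'
#' Sequences are uppercased; record order is preserved; duplicate ids and
#' empty records are errors.
#'
#' @param path FASTA file path.
#' @return Data frame with `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- names(set)
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(set) == 0)) stop("empty FASTA record")
  data.frame(id = ids, sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write an id/sequence table to FASTA
#'
#' @param records Data frame with `id`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a tandem-repeat catalog in BED-like format
#'
#' Expects 0-based half-open intervals with the repeat motif in column 4.
#' Entries are validated (start < end, motif over {A,C,G,T}); malformed lines
#' are reported with their line number. Optional symmetric padding widens
#' each interval by `pad` bp on both sides (clamped at 0).
#'
#' @param path Catalog path (TSV: chrom, start, end, motif).
#' @param pad Non-negative padding in bp (default 0).
#' @return Data frame: `chrom`, `start`, `end`, `motif`, `locus_id`
#'   (chrom:start-end of the unpadded interval).
#' @export
read_catalog_bed <- function(path, pad = 0L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4) stop("malformed catalog line ", i, ": expected 4 columns")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) stop("malformed catalog line ", i,
                                         ": non-integer coordinates")
    if (start >= end) stop("malformed catalog line ", i, ": start >= end")
    if (grepl("[^ACGTacgt]", f[4])) stop("malformed catalog line ", i,
                                         ": motif not over {A,C,G,T}")
    data.frame(chrom = f[1], start = start, end = end, motif = toupper(f[4]),
               locus_id = sprintf("%s:%d-%d", f[1], start, end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (pad > 0) {
    out$start <- pmax(0L, out$start - as.integer(pad))
    out$end <- out$end + as.integer(pad)
  }
  out
}

#' Write a repeat catalog back to BED-like TSV
#'
#' @param catalog Data frame with `chrom`, `start`, `end`, `motif`.
#' @param path Output path.
#' @export
write_catalog_bed <- function(catalog, path) {
  write.table(catalog[, c("chrom", "start", "end", "motif")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a minimal SV VCF into a record table
#'
#' Parses a VCF 4.2 subset: biallelic records only (multiallelic ALTs are
#' rejected with a message), INFO keys SVTYPE/SVLEN/END, FORMAT fields
#' GT/AD/GP when present. VCF 1-based POS is converted to the package's
#' internal 0-based convention. A missing SVTYPE on an SV-length allele is
#' inferred from the allele lengths with a warning.
#'
#' @param path VCF path (plain text).
#' @return Data frame: `chrom`, `pos` (0-based), `end`, `svtype`, `svlen`,
#'   `genotype`, plus `allele_depth`/`genotype_posterior` when present.
#' @export
read_vcf_minimal <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF files")
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single records drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multiallelic records are not supported; split upstream")
  }
  info_get <- function(key) vcfR::extract.info(v, element = key)
  svtype <- info_get("SVTYPE")
  svlen <- suppressWarnings(as.integer(info_get("SVLEN")))
  endv <- suppressWarnings(as.integer(info_get("END")))
  pos <- as.integer(fix$POS) - 1L
  need <- is.na(svtype) & (nchar(fix$REF) >= 50 | nchar(fix$ALT) >= 50)
  if (any(need)) {
    warning("SVTYPE missing on SV-length allele; inferring from allele lengths")
    svtype[need] <- ifelse(nchar(fix$ALT[need]) > nchar(fix$REF[need]),
                           "INS", "DEL")
  }
  if (any(is.na(svlen))) {
    svlen[is.na(svlen)] <- nchar(fix$ALT[is.na(svlen)]) -
      nchar(fix$REF[is.na(svlen)])
  }
  endv[is.na(endv)] <- ifelse(svtype[is.na(endv)] == "DEL",
                              pos[is.na(endv)] + abs(svlen[is.na(endv)]),
                              pos[is.na(endv)])
  out <- data.frame(chrom = fix$CHROM, pos = pos, end = endv,
                    svtype = svtype, svlen = svlen, stringsAsFactors = FALSE)
  if (ncol(v@gt) >= 2) {
    gt <- vcfR::extract.gt(v, element = "GT")
    out$genotype <- gt[, 1]
    ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
    if (!is.null(ad) && !all(is.na(ad))) out$allele_depth <- ad[, 1]
    gp <- tryCatch(vcfR::extract.gt(v, element = "GP"), error = function(e) NULL)
    if (!is.null(gp) && !all(is.na(gp))) out$genotype_posterior <- gp[, 1]
  }
  rownames(out) <- NULL
  out
}

#' Write SV records as a minimal VCF
#'
#' Emits a VCF 4.2 subset round-trippable by [read_vcf_minimal()]: INFO
#' SVTYPE/SVLEN/END and FORMAT GT.
#'
#' @param records Data frame with `chrom`, `pos` (0-based), `end`, `svtype`,
#'   `svlen`, optional `genotype`.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @export
write_sv_vcf <- function(records, path, sample_name = "sample1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  gt <- if ("genotype" %in% names(records)) records$genotype else
    rep("./.", nrow(records))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(r$chrom, r$pos + 1L, ".", "N", sprintf("<%s>", r$svtype), ".",
          "PASS",
          sprintf("SVTYPE=%s;SVLEN=%d;END=%d", r$svtype, r$svlen, r$end),
          "GT", gt[i], sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
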
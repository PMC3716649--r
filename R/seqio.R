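# Readers/writers for the standard formats the pipeline touches, and the
# shared coordinate convention.
#
# Coordinates are 1-based inclusive on the supplied reference region.  Every
# user-facing position is a Reference Position (RP): internal position +
# rp_offset.  With rp_offset = 0 the region's own numbering is reported; a
# region excised from a longer deposited sequence sets rp_offset so printed
# RPs match the full-length numbering.

PHRED_OFFSET <- 33L

#' A set of quality-scored reads
#'
#' Lightweight columnar container for FASTQ records: parallel character
#' vectors of identifiers, bases and Phred+33 quality strings.
#'
#' @param id,seq,qual character vectors of equal length.
#' @return an object of class `fastq_set`.
#' @export
fastq_set <- function(id = character(), seq = character(), qual = character()) {
  stopifnot(length(id) == length(seq), length(id) == length(qual))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop(sprintf("record %d ('%s'): quality length != sequence length", bad[1L], id[bad[1L]]))
  structure(list(id = as.character(id), seq = toupper(as.character(seq)),
                 qual = as.character(qual)),
            class = "fastq_set")
}

#' @export
length.fastq_set <- function(x) length(x$id)

#' @export
`[.fastq_set` <- function(x, i) fastq_set(x$id[i], x$seq[i], x$qual[i])

#' @export
print.fastq_set <- function(x, ...) {
  cat(sprintf("<fastq_set> %d reads", length(x)))
  if (length(x))
    cat(sprintf(", length %d-%d nt", min(nchar(x$seq)), max(nchar(x$seq))))
  cat("\n")
  invisible(x)
}

#' Phred quality integers for one read
#' @param qual a Phred+33 quality string.
#' @return integer vector of Phred scores.
#' @export
phred_scores <- function(qual) utf8ToInt(qual) - PHRED_OFFSET

#' Encode Phred integers as a Phred+33 string
#' @param q integer vector of Phred scores.
#' @export
phred_string <- function(q) intToUtf8(as.integer(q) + PHRED_OFFSET)

#' Read a FASTQ file
#'
#' Strict four-line-record FASTQ (Phred+33).  Malformed records raise an
#' error naming the record index.
#'
#' @param path file path.
#' @return a [fastq_set].
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(fastq_set())
  if (length(lines) %% 4L != 0L)
    stop("FASTQ line count not a multiple of 4 (truncated record at end?)")
  n <- length(lines) %/% 4L
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad)) stop(sprintf("record %d: header does not start with '@'", bad[1L]))
  bad <- which(!startsWith(pl, "+"))
  if (length(bad)) stop(sprintf("record %d: separator does not start with '+'", bad[1L]))
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) stop(sprintf("record %d: quality length != sequence length", bad[1L]))
  fastq_set(sub("^@", "", sub("\\s.*$", "", hd)), sq, ql)
}

#' Write a FASTQ file
#' @param reads a [fastq_set].
#' @param path file path.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- character(4L * length(reads))
  out[seq(1L, by = 4L, length.out = length(reads))] <- paste0("@", reads$id)
  out[seq(2L, by = 4L, length.out = length(reads))] <- reads$seq
  out[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = length(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' A reference region
#'
#' The reference sequence the pooled reads are aligned to, with the RP
#' offset and the RP of the start codon.
#'
#' @param name region name.
#' @param sequence uppercase DNA string.
#' @param rp_offset integer added to internal 1-based positions to report RPs.
#' @param cds_start_rp RP of the first base of the start codon (ATG), or NA
#'   for a non-coding region.
#' @return an object of class `reference_region`.
#' @export
reference_region <- function(name, sequence, rp_offset = 0L, cds_start_rp = NA_integer_) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty reference sequence")
  if (grepl("[^ACGTNRYSWKMBDHV]", sequence)) stop("non-IUPAC character in reference")
  rp_offset <- as.integer(rp_offset)
  if (!is.na(cds_start_rp)) {
    i <- as.integer(cds_start_rp) - rp_offset
    if (i < 1L || i + 2L > nchar(sequence))
      stop("cds_start_rp outside region")
    if (substr(sequence, i, i + 2L) != "ATG")
      stop("no ATG at cds_start_rp")
  }
  structure(list(name = name, sequence = sequence, rp_offset = rp_offset,
                 cds_start_rp = as.integer(cds_start_rp)),
            class = "reference_region")
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf("<reference_region> %s: %d nt, RP %d-%d, CDS start RP %s\n",
              x$name, nchar(x$sequence), x$rp_offset + 1L,
              x$rp_offset + nchar(x$sequence),
              ifelse(is.na(x$cds_start_rp), "NA", x$cds_start_rp)))
  invisible(x)
}

# internal <-> reported coordinates
rp_to_internal <- function(region, rp) as.integer(rp) - region$rp_offset
internal_to_rp <- function(region, pos) as.integer(pos) + region$rp_offset

#' Amplicon definitions
#'
#' @param pair_name names like "F2/R2".
#' @param fwd,rev primer sequences (IUPAC degeneracy allowed).
#' @param rp_start,rp_end expected RP interval of the amplified product
#'   (primers included).
#' @return data.frame of class `amplicon_set`.
#' @export
amplicon_set <- function(pair_name, fwd, rev, rp_start, rp_end) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (any(nchar(fwd) < 17L | nchar(fwd) > 25L) || any(nchar(rev) < 17L | nchar(rev) > 25L))
    stop("primers must be 17-25 nt")
  if (any(rp_start >= rp_end)) stop("amplicon interval start must precede end")
  out <- data.frame(pair_name = pair_name, fwd = fwd, rev = rev,
                    rp_start = as.integer(rp_start), rp_end = as.integer(rp_end),
                    stringsAsFactors = FALSE)
  class(out) <- c("amplicon_set", "data.frame")
  out
}

#' Read amplicon definitions from TSV (pair_name, fwd, rev, rp_start, rp_end)
#' @param path file path.
#' @export
read_amplicons <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  amplicon_set(d$pair_name, d$fwd, d$rev, d$rp_start, d$rp_end)
}

#' Read a reference allele panel from FASTA
#'
#' Headers are "allele_name genome=X note" with X in A/B/D/unassigned;
#' missing genome tags default to "unassigned".
#' @param path file path.
#' @return data.frame with allele_name, genome_label, sequence, note.
#' @export
read_allele_panel <- function(path) {
  x <- Biostrings::readBStringSet(path)
  hdr <- names(x)
  nm <- sub("\\s.*$", "", hdr)
  if (anyDuplicated(nm)) stop("duplicate allele names in panel")
  gl <- ifelse(grepl("genome=([ABD])", hdr),
               sub(".*genome=([ABD]).*", "\\1", hdr), "unassigned")
  data.frame(allele_name = nm, genome_label = gl,
             sequence = toupper(as.character(x)),
             note = sub("^\\S+\\s*", "", hdr), stringsAsFactors = FALSE)
}

#' Write the combined SNP/indel report as TSV
#'
#' One row per (RP, event), sorted by RP then alt; per-library frequency (%)
#' and depth columns; "." for a library without pileup coverage at the RP.
#'
#' @param combined the `table` element of [combine_reports()] output (or any
#'   data.frame with rp/type/ref/alt plus `freq_<lib>`/`depth_<lib>` columns).
#' @param path file path.
#' @export
write_variant_report <- function(combined, path) {
  d <- as.data.frame(combined)
  if (nrow(d)) {
    key <- paste(d$rp, d$type, d$alt)
    if (anyDuplicated(key)) stop("duplicate (RP, type, alt) rows in report")
    d <- d[order(d$rp, d$type, d$alt), , drop = FALSE]
    num <- vapply(d, is.numeric, TRUE) & grepl("^freq_", names(d))
    for (j in which(num)) d[[j]] <- round(d[[j]], 4L)
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' Read back a variant report written by [write_variant_report()]
#' @param path file path.
#' @export
read_variant_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
}

#' Export calls as minimal VCF 4.2 (secondary writer)
#'
#' One ALT per line; per-library frequencies as an AF-style INFO field.
#' Indels are re-anchored to the VCF convention (base before the event).
#'
#' @param combined combined call table (as for [write_variant_report()]).
#' @param region the [reference_region()].
#' @param path file path.
#' @export
write_vcf <- function(combined, region, path) {
  d <- as.data.frame(combined)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", region$name, nchar(region$sequence)),
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency (max across libraries, fraction)\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(d) == 0L) return(invisible(path))
  d <- d[order(d$rp), , drop = FALSE]
  fq <- d[, grepl("^freq_", names(d)), drop = FALSE]
  af <- if (ncol(fq)) apply(fq, 1L, function(x) max(x, na.rm = TRUE)) / 100 else rep(NA_real_, nrow(d))
  for (i in seq_len(nrow(d))) {
    ip <- rp_to_internal(region, d$rp[i])
    if (d$type[i] == "snp") {
      pos <- d$rp[i]; ref <- d$ref[i]; alt <- d$alt[i]
    } else if (startsWith(d$alt[i], "-")) {        # deletion
      pos <- d$rp[i] - 1L
      anc <- substr(region$sequence, ip - 1L, ip - 1L)
      ref <- paste0(anc, sub("^-", "", d$alt[i])); alt <- anc
    } else {                                       # insertion (anchored after rp)
      pos <- d$rp[i]
      anc <- substr(region$sequence, ip, ip)
      ref <- anc; alt <- paste0(anc, sub("^\\+", "", d$alt[i]))
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAF=%.6f",
                       region$name, pos, ref, alt, af[i]), con)
  }
  invisible(path)
}
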
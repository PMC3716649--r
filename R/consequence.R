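# Protein-consequence annotation: translate variants against the reference
# CDS frame, detect null (premature stop) mutations and amino-acid changes,
# locate changes in named motifs, and classify SNPs by codon position.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# translate a DNA string in frame 1; partial terminal codon dropped
translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "solve"))
}

#' Motif definitions on the reference protein
#'
#' Motifs are located either by a literal amino-acid string (`pattern`) or
#' by a fixed residue interval (`interval`), the latter for regions treated
#' as domains rather than exact strings.  Defaults cover the two N-terminal
#' GA-signal motifs of DELLA proteins: the DELLA region (a configured
#' residue interval, by default residues 40-75 of the reference protein,
#' taken from the deposited allele annotations rather than printed
#' coordinates) and the literal "TVHYNP" motif, plus the C-terminal GRAS
#' domain as a configurable interval.
#'
#' @param ... named motif specifications, each `list(pattern=)` or
#'   `list(interval=c(start, end))` in reference-protein residues.
#' @export
motif_set <- function(...) {
  m <- list(...)
  if (length(m) == 0L)
    m <- list(DELLA = list(interval = c(40L, 75L)),
              TVHYNP = list(pattern = "TVHYNP"),
              GRAS = list(interval = c(200L, 620L)))
  for (nm in names(m)) {
    spec <- m[[nm]]
    if (!is.null(spec$pattern) && grepl("[^A-Z*]", spec$pattern))
      stop("motif pattern must be uppercase amino acids: ", nm)
    if (is.null(spec$pattern) && is.null(spec$interval))
      stop("motif needs a pattern or an interval: ", nm)
  }
  structure(m, class = "motif_set")
}

# residue intervals of each motif on a protein sequence
locate_motifs <- function(motifs, protein) {
  out <- list()
  for (nm in names(motifs)) {
    spec <- motifs[[nm]]
    if (!is.null(spec$pattern)) {
      hits <- gregexpr(spec$pattern, protein, fixed = TRUE)[[1L]]
      if (hits[1L] != -1L)
        out[[nm]] <- cbind(start = as.integer(hits),
                           end = as.integer(hits) + nchar(spec$pattern) - 1L)
    } else {
      out[[nm]] <- cbind(start = spec$interval[1L], end = spec$interval[2L])
    }
  }
  out
}

reference_protein <- function(region) {
  if (is.na(region$cds_start_rp)) stop("region has no CDS start")
  cds0 <- rp_to_internal(region, region$cds_start_rp)
  translate_dna(substr(region$sequence, cds0, nchar(region$sequence)))
}

#' Annotate a single SNP call against the reference CDS
#'
#' @param rp SNP reference position.
#' @param ref,alt reference and alternate base.
#' @param region a [reference_region()] with `cds_start_rp` set.
#' @param motifs a [motif_set()].
#' @return one-row data.frame: rp, cds_nt, codon_index, codon_pos,
#'   ref_codon, alt_codon, ref_aa, alt_aa, class, motif.  A SNP upstream of
#'   the CDS is annotated class "utr5" with NA codon fields.
#' @export
annotate_snp <- function(rp, ref, alt, region, motifs = motif_set()) {
  pos <- rp_to_internal(region, rp)
  cds0 <- rp_to_internal(region, region$cds_start_rp)
  if (pos < cds0) {
    return(data.frame(rp = rp, cds_nt = NA_integer_, codon_index = NA_integer_,
                      codon_pos = NA_integer_, ref_codon = NA_character_,
                      alt_codon = NA_character_, ref_aa = NA_character_,
                      alt_aa = NA_character_, class = "utr5",
                      motif = NA_character_, stringsAsFactors = FALSE))
  }
  cds_nt <- pos - cds0 + 1L
  codon_index <- (cds_nt - 1L) %/% 3L + 1L
  codon_pos <- (cds_nt - 1L) %% 3L + 1L
  cstart <- cds0 + 3L * (codon_index - 1L)
  ref_codon <- substr(region$sequence, cstart, cstart + 2L)
  if (substr(ref_codon, codon_pos, codon_pos) != toupper(ref))
    stop(sprintf("ref base mismatch at RP %d", rp))
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- toupper(alt)
  ref_aa <- translate_dna(ref_codon)
  alt_aa <- translate_dna(alt_codon)
  class <- if (alt_codon %in% STOP_CODONS) "nonsense"
           else if (ref_aa == alt_aa) "synonymous" else "missense"
  prot <- reference_protein(region)
  occ <- locate_motifs(motifs, prot)
  motif <- NA_character_
  for (nm in names(occ))
    if (any(occ[[nm]][, "start"] <= codon_index & codon_index <= occ[[nm]][, "end"])) {
      motif <- nm
      break
    }
  data.frame(rp = rp, cds_nt = cds_nt, codon_index = codon_index,
             codon_pos = codon_pos, ref_codon = ref_codon,
             alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
             class = class, motif = motif, stringsAsFactors = FALSE)
}

#' Protein-level diff of an amplicon variant
#'
#' Translates the CDS-overlapping portion of the variant consensus in the
#' reference frame and reports the net nucleotide change, frameshift or
#' in-frame status, premature stop (truncation codon, in reference-protein
#' numbering), and inserted/deleted/substituted residues from a global
#' protein alignment.
#'
#' @param variant one row of an `amplicon_variants` table (or a list with
#'   `consensus` and `event_string`).
#' @param region a [reference_region()].
#' @param rp_start RP of the first base of the consensus.
#' @return list: net_nt, class ("identical", "substitutions_only",
#'   "inframe_indel", "frameshift"), premature_stop, truncation_codon,
#'   aa_deleted, aa_inserted, aa_substitutions.
#' @export
annotate_variant_protein <- function(variant, region, rp_start) {
  cds0 <- rp_to_internal(region, region$cds_start_rp)
  s <- rp_to_internal(region, rp_start)
  consensus <- variant$consensus
  et <- parse_edit_string(variant$event_string)
  net <- if (nrow(et)) sum(nchar(et$alt) - nchar(et$ref)) else 0L
  # advance to the first complete codon within the consensus
  skip <- if (s >= cds0) (3L - (s - cds0) %% 3L) %% 3L else cds0 - s
  refseg <- substr(region$sequence, s, nchar(region$sequence))
  first_codon <- (s + skip - cds0) %/% 3L + 1L
  vprot <- translate_dna(substr(consensus, skip + 1L, nchar(consensus)))
  rprot <- translate_dna(substr(refseg, skip + 1L,
                                min(nchar(refseg), nchar(consensus) - net + 6L)))
  premature <- grepl("\\*", sub("\\*$", "", vprot))
  trunc <- if (premature)
    first_codon + as.integer(regexpr("*", vprot, fixed = TRUE)) - 1L else NA_integer_
  class <- if (nrow(et) == 0L) "identical"
           else if (net %% 3L != 0L) "frameshift"
           else if (any(et$type != "snp")) "inframe_indel"
           else "substitutions_only"
  # residue-level diff (meaningful for in-frame variants)
  aa_del <- character(); aa_ins <- character(); aa_sub <- character()
  if (class %in% c("inframe_indel", "substitutions_only") && nchar(vprot) && nchar(rprot)) {
    vp <- sub("\\*.*$", "", vprot)
    rp2 <- substr(rprot, 1L, nchar(vp) + abs(net) %/% 3L + 2L)
    pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(vp),
                                        Biostrings::AAString(rp2),
                                        type = "overlap",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 4)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    q <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    ri <- first_codon - 1L + cumsum(q != "-")
    aa_del <- paste0(q[p == "-"], ri[p == "-"])
    aa_ins <- paste0(ri[q == "-"], "+", p[q == "-"])
    mm <- which(p != q & p != "-" & q != "-")
    aa_sub <- paste0(q[mm], ri[mm], p[mm])
  }
  list(net_nt = as.integer(net), class = class, premature_stop = premature,
       truncation_codon = trunc, aa_deleted = aa_del, aa_inserted = aa_ins,
       aa_substitutions = aa_sub)
}

#' Tally consequence records
#'
#' @param records data.frame of [annotate_snp()] rows.
#' @return list: total coding SNPs, synonymous, nonsynonymous (missense +
#'   nonsense), counts by class, and nonsynonymous counts by codon position.
#' @export
tally_consequences <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(list(coding = 0L, synonymous = 0L, nonsynonymous = 0L,
                by_class = integer(),
                by_codon_pos = c(`1` = 0L, `2` = 0L, `3` = 0L)))
  }
  coding <- records[records$class != "utr5", , drop = FALSE]
  nonsyn <- coding[coding$class %in% c("missense", "nonsense"), , drop = FALSE]
  by_pos <- vapply(1:3, function(p) sum(nonsyn$codon_pos == p), 1L)
  names(by_pos) <- as.character(1:3)
  list(coding = nrow(coding),
       synonymous = sum(coding$class == "synonymous"),
       nonsynonymous = nrow(nonsyn),
       by_class = table(coding$class),
       by_codon_pos = by_pos)
}
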
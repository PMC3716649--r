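# Putative spliceosomal intron detection.
#
# A reading-frame disruption (net indel not a multiple of 3, or a premature
# stop) in an amplicon variant suggests a retained intron.  Candidate
# intervals on the variant consensus whose in-silico removal (i) restores
# the reference reading frame and (ii) leaves no premature stop are
# enumerated exhaustively up to max_len; candidates with GT..AG boundary
# dinucleotides are canonical spliceosomal introns and rank above
# non-canonical ones (e.g. AC..AT).  Splicing may legitimately delete
# reference codons next to the splice site, so interval removal is allowed
# to shorten the coding sequence in multiples of 3.

# fast vectorised check/translation helpers
codon_starts <- function(n) if (n >= 3L) seq.int(1L, n - 2L, by = 3L) else integer()

fast_translate <- function(seq) {
  st <- codon_starts(nchar(seq))
  if (!length(st)) return("")
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[substring(seq, st, st + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reading-frame disruption report for an amplicon variant
#'
#' @param variant a row of an `amplicon_variants` table (consensus +
#'   event_string).
#' @param region the [reference_region()].
#' @param rp_start RP of the first consensus base.
#' @return list: net_nt (net coding-length change), frame_residue (net mod
#'   3), premature_stop, first_stop_codon (reference-protein numbering or
#'   NA), disrupted.
#' @export
detect_frame_disruption <- function(variant, region, rp_start) {
  ann <- annotate_variant_protein(variant, region, rp_start)
  res <- ((ann$net_nt %% 3L) + 3L) %% 3L
  list(net_nt = ann$net_nt, frame_residue = res,
       premature_stop = ann$premature_stop,
       first_stop_codon = ann$truncation_codon,
       disrupted = res != 0L || ann$premature_stop)
}

#' Scan an amplicon variant for putative spliceosomal introns
#'
#' Exhaustive enumeration of intervals (length 4..max_len) on the variant
#' consensus whose removal restores the reading frame and removes all
#' premature stops.  Survivors are ranked by `spliced_identity`: the
#' fraction of reference codons of the amplicon that the spliced sequence
#' reproduces in frame (codon positions projected through the variant's
#' event list).  This penalises leftover frameshifted stretches, leftover
#' insertion bases and deleted reference codons symmetrically, so the
#' genuine retained intron outranks both near-miss shifts and large
#' self-consistent removals.  Ties break canonical (GT..AG) before
#' non-canonical, then leftmost, then shortest.
#'
#' @param variant a row of an `amplicon_variants` table.
#' @param region the [reference_region()].
#' @param rp_start RP of the first consensus base.
#' @param max_len maximum intron length considered.
#' @param min_identity drop candidates whose spliced sequence matches the
#'   correspondingly shortened reference below this fraction (0 keeps all;
#'   the pipeline uses 0.7 to suppress remove-anything candidates while
#'   tolerating homeolog divergence in the consensus).
#' @return data.table: rank, start, end (variant-consensus coordinates),
#'   rp_start, rp_end (projected reference positions), length, donor,
#'   acceptor, class, frame_restored, stops_removed, residues_deleted,
#'   spliced_identity.
#' @export
scan_introns <- function(variant, region, rp_start, max_len = 200L,
                         min_identity = 0) {
  empty <- data.table::data.table(rank = integer(), start = integer(),
    end = integer(), rp_start = integer(), rp_end = integer(),
    length = integer(), donor = character(), acceptor = character(),
    class = character(), frame_restored = logical(),
    stops_removed = logical(), residues_deleted = integer(),
    spliced_identity = numeric())
  seq <- variant$consensus
  n <- nchar(seq)
  et_rp <- parse_edit_string(variant$event_string)
  net <- if (nrow(et_rp)) sum(nchar(et_rp$alt) - nchar(et_rp$ref)) else 0L
  s <- rp_to_internal(region, rp_start)
  cds0 <- rp_to_internal(region, region$cds_start_rp)
  skip <- if (s >= cds0) (3L - (s - cds0) %% 3L) %% 3L else cds0 - s
  # projection of consensus positions onto the (local) reference segment,
  # through the variant's own event list
  local_et0 <- if (nrow(et_rp)) {
    edit_table(rp_to_internal(region, et_rp$pos) - s + 1L, et_rp$ref, et_rp$alt)
  } else empty_edits()
  inv0 <- invert_edits(local_et0)          # consensus -> reference-segment
  reflen_seg <- n - net
  refseg <- substr(region$sequence, s, s + reflen_seg - 1L)
  proj <- c(pmin(pmax(map_ref_pos(inv0, seq_len(n), side = "right"), 1L),
                 reflen_seg + 1L), reflen_seg + 1L)
  cch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  # reference codon-boundary phase in local coordinates
  bmod <- (skip + 1L) %% 3L
  n_ref_codons <- max(1L, (reflen_seg - skip) %/% 3L)
  lens <- seq.int(4L, min(max_len, n - 1L))
  lens <- lens[(net - lens) %% 3L == 0L]
  if (!length(lens)) return(empty)
  rows <- vector("list", 256L); nr <- 0L
  for (L in lens) {
    for (i in seq_len(n - L + 1L)) {
      j <- i + L - 1L
      ns <- n - L                          # spliced length
      st <- seq.int(skip + 1L, ns - 2L, by = 3L)
      if (!length(st)) next
      # spliced coordinate -> consensus coordinate
      c1 <- ifelse(st < i, st, st + L)
      c2 <- ifelse(st + 1L < i, st + 1L, st + 1L + L)
      c3 <- ifelse(st + 2L < i, st + 2L, st + 2L + L)
      codon_sp <- paste0(cch[c1], cch[c2], cch[c3])
      if (any(codon_sp[-length(codon_sp)] %in% STOP_CODONS)) next
      p1 <- proj[c1]; p3 <- proj[c3]
      aligned <- (p1 %% 3L == bmod) & (p3 == p1 + 2L) & (p1 + 2L <= reflen_seg)
      ident <- sum(aligned & codon_sp == substring(refseg, p1, p1 + 2L)) /
        n_ref_codons
      if (ident < min_identity) next
      don <- substr(seq, i, i + 1L)
      acc <- substr(seq, j - 1L, j)
      nr <- nr + 1L
      if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nr]] <- data.table::data.table(
        start = i, end = j, length = L, donor = don, acceptor = acc,
        class = if (don == "GT" && acc == "AG") "canonical" else "non_canonical",
        frame_restored = TRUE, stops_removed = TRUE,
        residues_deleted = as.integer((proj[j + 1L] - proj[i]) %/% 3L),
        spliced_identity = ident)
    }
  }
  if (nr == 0L) return(empty)
  out <- data.table::rbindlist(rows[seq_len(nr)])
  # project interval boundaries onto reference coordinates
  out[, rp_start := internal_to_rp(region, map_ref_pos(inv0, start, side = "right") + s - 1L)]
  out[, rp_end := internal_to_rp(region, map_ref_pos(inv0, end, side = "left") + s - 1L)]
  data.table::setorder(out, -spliced_identity, class, start, length)
  out[, rank := seq_len(.N)]
  data.table::setcolorder(out, c("rank", "start", "end", "rp_start", "rp_end",
                                 "length", "donor", "acceptor", "class",
                                 "frame_restored", "stops_removed",
                                 "residues_deleted", "spliced_identity"))
  out[]
}

#' Splice intron calls out of a variant and translate
#'
#' @param variant a row of an `amplicon_variants` table.
#' @param calls data.frame of intron calls (columns start, end on the
#'   variant consensus); must be non-overlapping.
#' @param region the [reference_region()].
#' @param rp_start RP of the first consensus base.
#' @return list: spliced (DNA), protein (translated in the reference
#'   frame).
#' @export
splice_and_translate <- function(variant, calls, region, rp_start) {
  seq <- variant$consensus
  if (!is.null(calls) && nrow(calls)) {
    calls <- calls[order(calls$start), , drop = FALSE]
    if (any(calls$start[-1L] <= calls$end[-nrow(calls)]))
      stop("overlapping intron calls")
    for (i in rev(seq_len(nrow(calls))))
      seq <- paste0(substr(seq, 1L, calls$start[i] - 1L),
                    substr(seq, calls$end[i] + 1L, nchar(seq)))
  }
  s <- rp_to_internal(region, rp_start)
  cds0 <- rp_to_internal(region, region$cds_start_rp)
  skip <- if (s >= cds0) (3L - (s - cds0) %% 3L) %% 3L else cds0 - s
  list(spliced = seq,
       protein = fast_translate(substr(seq, skip + 1L, nchar(seq))))
}
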
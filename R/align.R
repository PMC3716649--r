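# Reference-guided semi-global alignment of pooled amplicon reads and
# per-position pileup construction.
#
# Reads are aligned end-to-end (pattern-global) against a locally free
# reference (subject ends unpenalised) under affine gap scoring, in both
# orientations.  Scoring must tolerate homeolog divergence (~95% identity
# between subgenome copies) while rejecting off-target product, hence the
# permissive default identity threshold of 0.80.  Indels are left-aligned
# within repeat runs so that one event aggregates at a single reference
# position.

#' Alignment configuration
#'
#' Scores follow the convention that a gap of length L costs
#' `gap_open + L * gap_ext`.
#'
#' @param match,mismatch per-column scores.
#' @param gap_open,gap_ext affine gap costs (positive numbers).
#' @param min_identity alignments below this identity (matches / aligned
#'   columns) are reported unaligned.
#' @export
align_config <- function(match = 1, mismatch = -2, gap_open = 4, gap_ext = 1,
                         min_identity = 0.72) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_ext > 0,
            min_identity >= 0, min_identity <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, min_identity = min_identity),
            class = "align_config")
}

# substitution matrix over A/C/G/T/N; N never matches anything
subst_matrix <- function(cfg) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(cfg$mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m) <- cfg$match
  m["N", "N"] <- cfg$mismatch
  m
}

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# mismatches between a read prefix and a (possibly degenerate) primer
iupac_prefix_mismatch <- function(seq, primer) {
  n <- nchar(primer)
  if (nchar(seq) < n) return(n)
  s <- strsplit(substr(seq, 1L, n), "", fixed = TRUE)[[1L]]
  p <- strsplit(primer, "", fixed = TRUE)[[1L]]
  exp <- Biostrings::IUPAC_CODE_MAP[p]
  exp[is.na(exp)] <- ""
  sum(!mapply(grepl, s, exp, MoreArgs = list(fixed = TRUE)))
}

# assign each read to (amplicon, strand) by primer prefix; NA when no primer
# matches within max_mismatch
demux_reads <- function(reads, amplicons, max_mismatch = 3L) {
  n <- length(reads)
  amp <- rep(NA_integer_, n); strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    best <- max_mismatch + 1L
    for (k in seq_len(nrow(amplicons))) {
      mm1 <- iupac_prefix_mismatch(s, amplicons$fwd[k])  # forward read
      if (mm1 < best) { best <- mm1; amp[i] <- k; strand[i] <- "+" }
      mm2 <- iupac_prefix_mismatch(s, amplicons$rev[k])  # reverse read
      if (mm2 < best) { best <- mm2; amp[i] <- k; strand[i] <- "-" }
    }
    if (best > max_mismatch) { amp[i] <- NA_integer_; strand[i] <- NA_character_ }
  }
  data.table::data.table(idx = seq_len(n), amp = amp, strand = strand)
}

# clip alignment ends that are not anchored by a clean run of matches: a
# read end with nothing homologous to align to (e.g. one starting inside a
# long insertion) smears across the reference; assembly pipelines clip
# such ends.  Amplicon reads begin with primer-identical bases, so a
# well-placed read keeps both ends.
clip_bounds <- function(m, w = 12L) {
  n <- length(m)
  if (n < w) return(if (all(m)) c(1L, n) else c(1L, 0L))
  run <- cumsum(m)
  ok <- which(m & c(run[w:n] - c(0L, run[seq_len(n - w)]) == w, rep(FALSE, w - 1L)))
  if (!length(ok)) return(c(1L, 0L))
  lo <- ok[1L]
  hi <- ok[length(ok)] + w - 1L
  c(lo, hi)
}

# parse one alignment into edit-table events (internal reference
# coordinates) plus bookkeeping, from the fast PairwiseAlignments
# accessors: mism_* from mismatchTable (pattern position, absolute subject
# position, bases).  insertion()/deletion() report each range with the
# widths of PREVIOUS same-type gaps subtracted; convert both to true
# alignment-column coordinates before doing any arithmetic.
pa_to_events <- function(read_seq, st_p, en_p, st_s, offset,
                         ins_s, ins_w, del_s, del_w,
                         mism_p, mism_sub, mism_ref, mism_alt, refseq) {
  if (length(ins_s) > 1L)
    ins_s <- ins_s + cumsum(c(0L, ins_w[-length(ins_w)]))
  if (length(del_s) > 1L)
    del_s <- del_s + cumsum(c(0L, del_w[-length(del_w)]))
  plen <- en_p - st_p + 1L
  n_col <- plen + sum(del_w)
  m <- rep(TRUE, n_col)
  for (k in seq_along(ins_s)) m[ins_s[k]:(ins_s[k] + ins_w[k] - 1L)] <- FALSE
  for (k in seq_along(del_s)) m[del_s[k]:(del_s[k] + del_w[k] - 1L)] <- FALSE
  # mismatch pattern positions -> columns (insert the deletion gap blocks)
  mm_col <- mism_p - st_p + 1L
  for (k in seq_along(del_s)) mm_col[mm_col >= del_s[k]] <- mm_col[mm_col >= del_s[k]] + del_w[k]
  m[mm_col] <- FALSE
  cb <- clip_bounds(m)
  ins_before <- function(col) { w <- ins_w[ins_s < col]; sum(w) }
  del_before <- function(col) { w <- del_w[del_s < col]; sum(w) }
  clip5 <- if (cb[1L] > 1L) (cb[1L] - 1L) - del_before(cb[1L]) else 0L
  clip3 <- if (cb[2L] >= cb[1L]) n_col - cb[2L] - (sum(del_w) - del_before(cb[2L] + 1L)) else plen
  if (cb[2L] < cb[1L] + 29L)
    return(list(events = data.table::data.table(pos = integer(),
                  ref = character(), alt = character()),
                n_col = n_col, n_match = 0L,
                rp_start = offset + st_s, rp_end = offset + st_s,
                clip5 = clip5, clip3 = clip3, ok = FALSE))
  lo <- cb[1L]; hi <- cb[2L]
  rp_start <- offset + st_s + (lo - 1L) - ins_before(lo)
  rp_end <- offset + st_s - 1L + hi - ins_before(hi + 1L)
  n_match <- sum(m[lo:hi])
  ev_pos <- integer(); ev_ref <- character(); ev_alt <- character()
  keep_mm <- mm_col >= lo & mm_col <= hi
  if (any(keep_mm)) {
    ev_pos <- offset + mism_sub[keep_mm]
    ev_ref <- mism_ref[keep_mm]; ev_alt <- mism_alt[keep_mm]
  }
  for (k in seq_along(ins_s)) {
    if (ins_s[k] < lo || ins_s[k] > hi) next
    ps <- st_p + (ins_s[k] - 1L) - del_before(ins_s[k])
    anchor <- offset + st_s - 1L + (ins_s[k] - 1L) - ins_before(ins_s[k])
    ev_pos <- c(ev_pos, anchor)
    ev_ref <- c(ev_ref, "")
    ev_alt <- c(ev_alt, substr(read_seq, ps, ps + ins_w[k] - 1L))
  }
  for (k in seq_along(del_s)) {
    if (del_s[k] < lo || del_s[k] > hi) next
    ss <- offset + st_s + (del_s[k] - 1L) - ins_before(del_s[k])
    ev_pos <- c(ev_pos, ss)
    ev_ref <- c(ev_ref, substr(refseq, ss, ss + del_w[k] - 1L))
    ev_alt <- c(ev_alt, "")
  }
  list(events = data.table::data.table(pos = as.integer(ev_pos),
                                       ref = ev_ref, alt = ev_alt),
       n_col = hi - lo + 1L, n_match = n_match,
       rp_start = rp_start, rp_end = rp_end,
       clip5 = clip5, clip3 = clip3, ok = TRUE)
}

# left-align one read's indel events within repeat runs, bounded below by
# the read's aligned start and blocked by neighbouring events
left_align_events <- function(ev, refseq, rp_start) {
  if (nrow(ev) == 0L) return(ev)
  ev <- ev[order(ev$pos)]
  type <- ifelse(ev$ref == "", "ins", ifelse(ev$alt == "", "del", "snp"))
  for (i in seq_len(nrow(ev))) {
    lower <- if (i > 1L) ev$pos[i - 1L] + max(nchar(ev$ref[i - 1L]), 1L) else rp_start
    if (type[i] == "del") {
      len <- nchar(ev$ref[i])
      while (ev$pos[i] > lower &&
             substr(refseq, ev$pos[i] - 1L, ev$pos[i] - 1L) ==
             substr(ev$ref[i], len, len)) {
        ev$pos[i] <- ev$pos[i] - 1L
        ev$ref[i] <- substr(refseq, ev$pos[i], ev$pos[i] + len - 1L)
      }
    } else if (type[i] == "ins") {
      len <- nchar(ev$alt[i])
      while (ev$pos[i] >= lower &&
             substr(refseq, ev$pos[i], ev$pos[i]) == substr(ev$alt[i], len, len)) {
        ev$alt[i] <- paste0(substr(refseq, ev$pos[i], ev$pos[i]),
                            substr(ev$alt[i], 1L, len - 1L))
        ev$pos[i] <- ev$pos[i] - 1L
      }
    }
  }
  ev
}

#' Align reads to a reference region
#'
#' Semi-global (read-global, reference-ends-free) affine-gap alignment; the
#' better of the two orientations is kept per read.  Reads whose identity
#' falls below `cfg$min_identity` are reported unaligned and excluded from
#' the event table.
#'
#' @param reads a [fastq_set].
#' @param region a [reference_region()].
#' @param cfg an [align_config()].
#' @param amplicons optional [amplicon_set()]; when given, reads are first
#'   demultiplexed by primer prefix (as amplicon pipelines do), which fixes
#'   their strand and restricts the dynamic programming to the amplicon's
#'   reference window.  Reads matching no primer fall back to full-length
#'   two-orientation alignment.
#' @param window_pad reference window padding around a demultiplexed
#'   amplicon interval.
#' @return an `alignment_set`: list with `reads` (data.table: read_id,
#'   strand, rp_start, rp_end, score, identity, aligned) and `events`
#'   (data.table: read_id, pos, ref, alt, type; internal coordinates,
#'   insertions anchored after `pos`).
#' @export
align_reads <- function(reads, region, cfg = align_config(), amplicons = NULL,
                        window_pad = 60L) {
  empty <- list(reads = data.table::data.table(
                  read_id = character(), strand = character(),
                  rp_start = integer(), rp_end = integer(), score = numeric(),
                  identity = numeric(), aligned = logical()),
                events = data.table::data.table(
                  read_id = character(), pos = integer(), ref = character(),
                  alt = character(), type = character()))
  attr(empty, "region_name") <- region$name
  class(empty) <- "alignment_set"
  if (length(reads) == 0L) return(empty)
  sm <- subst_matrix(cfg)
  refn <- nchar(region$sequence)
  n <- length(reads)
  rows <- vector("list", n)
  evs <- vector("list", n)

  process_one <- function(i, info, strand, sc) {
    identity <- info$n_match / info$n_col
    ok <- info$ok && identity >= cfg$min_identity
    rows[[i]] <<- data.table::data.table(
      read_id = reads$id[i], strand = strand,
      rp_start = info$rp_start, rp_end = info$rp_end, score = sc,
      identity = identity, clip5 = info$clip5, clip3 = info$clip3,
      aligned = ok)
    if (ok && nrow(info$events)) {
      ev <- left_align_events(info$events, region$sequence, info$rp_start)
      ev[, read_id := reads$id[i]]
      evs[[i]] <<- ev
    }
  }

  run_pa <- function(seqs, subj) {
    Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(seqs), subj,
                                  type = "global-local",
                                  substitutionMatrix = sm,
                                  gapOpening = cfg$gap_open,
                                  gapExtension = cfg$gap_ext)
  }

  extract_infos <- function(pa, seqs, offset) {
    st_p <- IRanges::start(Biostrings::pattern(pa))
    en_p <- IRanges::end(Biostrings::pattern(pa))
    st_s <- IRanges::start(Biostrings::subject(pa))
    ins <- Biostrings::insertion(pa); del <- Biostrings::deletion(pa)
    ins_s <- as.list(IRanges::start(ins)); ins_w <- as.list(IRanges::width(ins))
    del_s <- as.list(IRanges::start(del)); del_w <- as.list(IRanges::width(del))
    mt <- Biostrings::mismatchTable(pa)
    mm_idx <- split(seq_len(nrow(mt)),
                    factor(mt$PatternId, levels = seq_along(seqs)))
    lapply(seq_along(seqs), function(j) {
      r <- mm_idx[[j]]
      pa_to_events(seqs[j], st_p[j], en_p[j], st_s[j], offset,
                   ins_s[[j]], ins_w[[j]], del_s[[j]], del_w[[j]],
                   mt$PatternStart[r], mt$SubjectStart[r],
                   as.character(mt$SubjectSubstring[r]),
                   as.character(mt$PatternSubstring[r]),
                   region$sequence)
    })
  }

  align_group <- function(idx, seqs, subj, offset, strand) {
    pa <- run_pa(seqs, subj)
    sc <- Biostrings::score(pa)
    infos <- extract_infos(pa, seqs, offset)
    for (j in seq_along(idx))
      process_one(idx[j], infos[[j]], strand[j], sc[j])
  }

  dm <- if (!is.null(amplicons)) demux_reads(reads, amplicons)
        else data.table::data.table(idx = seq_len(n), amp = NA_integer_,
                                    strand = NA_character_)
  known <- dm[!is.na(dm$amp)]
  if (nrow(known)) {
    for (grp in split(known, by = c("amp", "strand"))) {
      if (nrow(grp) == 0L) next
      a <- grp$amp[1L]
      ws <- max(1L, rp_to_internal(region, amplicons$rp_start[a]) - window_pad)
      we <- min(refn, rp_to_internal(region, amplicons$rp_end[a]) + window_pad)
      subj <- Biostrings::DNAString(substr(region$sequence, ws, we))
      seqs <- reads$seq[grp$idx]
      if (grp$strand[1L] == "-") seqs <- revcomp(seqs)
      align_group(grp$idx, seqs, subj, ws - 1L, rep(grp$strand[1L], nrow(grp)))
    }
  }
  rest <- dm$idx[is.na(dm$amp)]
  if (length(rest)) {
    subj <- Biostrings::DNAString(region$sequence)
    seqs_f <- reads$seq[rest]
    seqs_r <- revcomp(seqs_f)
    pa_f <- run_pa(seqs_f, subj)
    pa_r <- run_pa(seqs_r, subj)
    sc_f <- Biostrings::score(pa_f)
    sc_r <- Biostrings::score(pa_r)
    use_rev <- sc_r > sc_f
    infos_f <- extract_infos(pa_f, seqs_f, 0L)
    infos_r <- extract_infos(pa_r, seqs_r, 0L)
    for (j in seq_along(rest)) {
      if (use_rev[j]) process_one(rest[j], infos_r[[j]], "-", sc_r[j])
      else process_one(rest[j], infos_f[[j]], "+", sc_f[j])
    }
  }
  out <- list(reads = data.table::rbindlist(rows),
              events = data.table::rbindlist(evs, use.names = TRUE))
  if (nrow(out$events) == 0L) {
    out$events <- empty$events
  } else {
    out$events[, type := ifelse(ref == "", "ins", ifelse(alt == "", "del", "snp"))]
    data.table::setcolorder(out$events, c("read_id", "pos", "ref", "alt", "type"))
  }
  attr(out, "region_name") <- region$name
  class(out) <- "alignment_set"
  out
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set> %d reads (%d aligned) vs %s, %d events\n",
              nrow(x$reads), sum(x$reads$aligned), attr(x, "region_name"),
              nrow(x$events)))
  invisible(x)
}

#' Reconstruct the (plus-strand) read sequence from its alignment record
#'
#' Round-trip check helper: applies a read's event list to the covered
#' reference interval.  The result equals the plus-strand read with any
#' clipped terminal bases (`clip5`/`clip3`) removed.
#' @param aln an `alignment_set`.
#' @param read_id read identifier.
#' @param region the [reference_region()] aligned against.
#' @export
reconstruct_read <- function(aln, read_id, region) {
  wanted <- read_id
  r <- aln$reads[aln$reads$read_id == wanted & aln$reads$aligned]
  if (nrow(r) != 1L) stop("read not aligned: ", wanted)
  ev <- aln$events[aln$events$read_id == wanted]
  local <- if (nrow(ev)) edit_table(ev$pos - r$rp_start + 1L, ev$ref, ev$alt) else empty_edits()
  apply_edits(substr(region$sequence, r$rp_start, r$rp_end), local)
}

#' Build per-position pileup columns from an alignment set
#'
#' @param aln an `alignment_set` (all against the same region).
#' @param region the [reference_region()].
#' @param amplicons optional [amplicon_set()]; read ends falling inside a
#'   primer interval have their primer-spanning bases masked out of the
#'   counts (primer synthesis overrides template variation).
#' @return a `pileup` object: list with `columns` (data.table: pos, depth,
#'   A, C, G, T, N, del) and `indels` (data.table: pos, type, seq, count;
#'   insertions anchored after pos, deletions starting at pos).  Positions
#'   with zero coverage are omitted.
#' @export
build_pileup <- function(aln, region, amplicons = NULL) {
  rd <- aln$reads[aln$reads$aligned]
  ev <- data.table::copy(aln$events)
  refch <- strsplit(region$sequence, "", fixed = TRUE)[[1L]]
  if (nrow(rd) == 0L) {
    return(structure(list(
      columns = data.table::data.table(pos = integer(), depth = integer(),
        A = integer(), C = integer(), G = integer(), T = integer(),
        N = integer(), del = integer()),
      indels = data.table::data.table(pos = integer(), type = character(),
        seq = character(), count = integer())),
      region_name = region$name, class = "pileup"))
  }
  # primer masks per read: positions excluded from this read's counts
  mask_lo <- rep(0L, nrow(rd))          # exclude pos <= mask_lo
  mask_hi <- rep(.Machine$integer.max, nrow(rd))  # exclude pos >= mask_hi
  if (!is.null(amplicons)) {
    for (k in seq_len(nrow(amplicons))) {
      fs <- rp_to_internal(region, amplicons$rp_start[k])
      fe <- fs + nchar(amplicons$fwd[k]) - 1L
      re <- rp_to_internal(region, amplicons$rp_end[k])
      rs <- re - nchar(amplicons$rev[k]) + 1L
      in_f <- rd$rp_start >= fs & rd$rp_start <= fe
      mask_lo[in_f] <- pmax(mask_lo[in_f], fe)
      in_r <- rd$rp_end >= rs & rd$rp_end <= re
      mask_hi[in_r] <- pmin(mask_hi[in_r], rs)
    }
  }
  cov <- data.table::data.table(
    read_id = rep(rd$read_id, rd$rp_end - rd$rp_start + 1L),
    pos = unlist(Map(seq.int, rd$rp_start, rd$rp_end)),
    lo = rep(mask_lo, rd$rp_end - rd$rp_start + 1L),
    hi = rep(mask_hi, rd$rp_end - rd$rp_start + 1L))
  cov <- cov[pos > lo & pos < hi]
  cov[, base := refch[pos]]
  if (nrow(ev)) {
    masks <- data.table::data.table(read_id = rd$read_id, lo = mask_lo, hi = mask_hi)
    ev <- masks[ev, on = "read_id"]
    ev <- ev[pos > lo & pos < hi]
    del <- ev[type == "del"]
    if (nrow(del)) {
      delpos <- data.table::data.table(
        read_id = rep(del$read_id, nchar(del$ref)),
        pos = unlist(Map(seq.int, del$pos, del$pos + nchar(del$ref) - 1L)))
      delpos[, isdel := TRUE]
      cov <- delpos[cov, on = c("read_id", "pos")]
      cov[isdel == TRUE, base := "-"]
      cov[, isdel := NULL]
    }
    snp <- ev[type == "snp"]
    if (nrow(snp)) {
      snp2 <- snp[, .(read_id, pos, alt)]
      cov <- snp2[cov, on = c("read_id", "pos")]
      cov[!is.na(alt), base := alt]
      cov[, alt := NULL]
    }
  }
  tab <- cov[, .N, by = .(pos, base)]
  wide <- data.table::dcast(tab, pos ~ base, value.var = "N", fill = 0L)
  for (b in c("A", "C", "G", "T", "N", "-"))
    if (!b %in% names(wide)) wide[, (b) := 0L]
  data.table::setnames(wide, "-", "del")
  wide[, depth := A + C + G + T + N + del]
  data.table::setcolorder(wide, c("pos", "depth", "A", "C", "G", "T", "N", "del"))
  data.table::setorder(wide, pos)
  indels <- if (nrow(ev) && nrow(ev[type != "snp"])) {
    ev[type != "snp", .(count = .N), by = .(pos, type, seq = ifelse(type == "ins", alt, ref))]
  } else {
    data.table::data.table(pos = integer(), type = character(),
                           seq = character(), count = integer())
  }
  data.table::setcolorder(indels, c("pos", "type", "seq", "count"))
  data.table::setorder(indels, pos, type, seq)
  structure(list(columns = wide[], indels = indels[]),
            region_name = region$name, class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d covered positions, depth %s, %d distinct indel events\n",
              attr(x, "region_name"), nrow(x$columns),
              if (nrow(x$columns)) sprintf("%d-%d", min(x$columns$depth), max(x$columns$depth)) else "-",
              nrow(x$indels)))
  invisible(x)
}

#' Export an alignment set as TSV (read, interval, op string, identity)
#' @param aln an `alignment_set`.
#' @param region the [reference_region()].
#' @param path file path.
#' @export
write_alignments <- function(aln, region, path) {
  rd <- as.data.frame(aln$reads)
  ops <- vapply(seq_len(nrow(rd)), function(i) {
    if (!rd$aligned[i]) return(".")
    ev <- aln$events[aln$events$read_id == rd$read_id[i]]
    if (nrow(ev) == 0L) return(sprintf("=%d", rd$rp_end[i] - rd$rp_start[i] + 1L))
    ev <- ev[order(ev$pos)]
    toks <- character(0); cur <- rd$rp_start[i]
    for (j in seq_len(nrow(ev))) {
      lead <- ev$pos[j] - cur + if (ev$type[j] == "ins") 1L else 0L
      if (lead > 0L) toks <- c(toks, sprintf("=%d", lead))
      toks <- c(toks, switch(ev$type[j],
        snp = paste0("X", ev$alt[j]),
        ins = paste0("I:", ev$alt[j]),
        del = sprintf("D%d", nchar(ev$ref[j]))))
      cur <- ev$pos[j] + if (ev$type[j] == "ins") 1L else max(nchar(ev$ref[j]), 1L)
    }
    if (cur <= rd$rp_end[i]) toks <- c(toks, sprintf("=%d", rd$rp_end[i] - cur + 1L))
    paste(toks, collapse = " ")
  }, "")
  out <- data.frame(read_id = rd$read_id, strand = rd$strand,
                    rp_start = internal_to_rp(region, rd$rp_start),
                    rp_end = internal_to_rp(region, rd$rp_end),
                    score = rd$score, identity = round(rd$identity, 4),
                    aligned = rd$aligned, ops = ops)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export pileup columns as TSV (one row per covered position, RP coords)
#' @param pile a `pileup`.
#' @param region the [reference_region()].
#' @param path file path.
#' @export
write_pileup <- function(pile, region, path) {
  d <- as.data.frame(pile$columns)
  d$rp <- internal_to_rp(region, d$pos)
  d <- d[, c("rp", setdiff(names(d), c("rp", "pos")))]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
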
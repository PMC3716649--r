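# Amplicon-variant (haplotype) reconstruction: reads sharing an identical
# linked string of accepted variant events form one amplicon variant, with
# a relative frequency among full-span reads; each variant is assigned to a
# genome/allele by alignment against a reference panel.

#' Haplotype-grouping configuration
#'
#' @param min_support variants with fewer supporting reads are merged into
#'   the nearest larger variant (or dropped when `merge_small` is FALSE).
#' @param min_span fraction of the amplicon interval a read must cover to
#'   vote (partial reads cannot be phased over the whole event string).
#' @param merge_small merge (TRUE) or drop (FALSE) under-supported variants.
#' @export
hap_config <- function(min_support = 2L, min_span = 0.95, merge_small = TRUE) {
  stopifnot(min_support >= 1L, min_span > 0, min_span <= 1)
  structure(list(min_support = as.integer(min_support), min_span = min_span,
                 merge_small = merge_small), class = "hap_config")
}

# accepted combined-report rows -> internal-coordinate edit keys
accepted_event_keys <- function(accepted, region) {
  if (nrow(accepted) == 0L) return(character())
  pos <- rp_to_internal(region, accepted$rp)
  ref <- ifelse(accepted$type == "snp", accepted$ref,
         ifelse(startsWith(accepted$alt, "-"), sub("^-", "", accepted$alt), ""))
  alt <- ifelse(accepted$type == "snp", accepted$alt,
         ifelse(startsWith(accepted$alt, "+"), sub("^\\+", "", accepted$alt), ""))
  paste(pos, ref, alt, sep = "|")
}

#' Group full-span reads into amplicon variants
#'
#' Reads covering at least `min_span` of the amplicon interval are grouped
#' by their event string restricted to accepted variant events (from
#' [combine_reports()] or a single library's calls); mismatches that did
#' not survive variant calling are treated as sequencing error and take the
#' reference base in the consensus.
#'
#' A haplotype carrying a long insertion yields a longer product, so reads
#' of a given length cover less of the reference and the plain full-span
#' rule under-counts exactly those variants.  Reads whose covered
#' reference interval plus inserted bases meets the span threshold are
#' therefore rescued: each is assigned to the unique variant whose event
#' string, restricted to the read's covered interval, equals the read's
#' own events (reads consistent with several variants are left out).
#'
#' @param aln an `alignment_set`.
#' @param region the [reference_region()].
#' @param rp_start,rp_end amplicon interval (RP coordinates).
#' @param accepted data.frame of accepted events (columns rp, type, ref,
#'   alt), e.g. `combined$table[combined$table$accepted, ]`.
#' @param cfg a [hap_config()].
#' @param pair_name amplicon name recorded on the result.
#' @return data.table of class `amplicon_variants`: variant_id, pair_name,
#'   event_string (RP coordinates), n_reads, freq (%), consensus.
#' @export
group_reads <- function(aln, region, rp_start, rp_end, accepted,
                        cfg = hap_config(), pair_name = "amplicon") {
  s <- rp_to_internal(region, rp_start)
  e <- rp_to_internal(region, rp_end)
  len <- e - s + 1L
  rd_all <- aln$reads[aln$reads$aligned]
  covered_all <- pmin(rd_all$rp_end, e) - pmax(rd_all$rp_start, s) + 1L
  # inserted bases each read carries inside the interval
  ins_all <- aln$events[aln$events$type == "ins" & aln$events$pos >= s &
                        aln$events$pos <= e,
                        .(ins_len = sum(nchar(alt))), by = read_id]
  ins_len_all <- stats::setNames(rep(0L, nrow(rd_all)), rd_all$read_id)
  ins_len_all[ins_all$read_id] <- ins_all$ins_len
  full <- covered_all >= cfg$min_span * len
  rescue <- !full & (covered_all + ins_len_all >= cfg$min_span * len) &
    covered_all > 0L
  rd <- rd_all[full]
  if (nrow(rd) == 0L) {
    warning("no full-span reads for amplicon ", pair_name)
    out <- data.table::data.table(variant_id = character(), pair_name = character(),
      event_string = character(), n_reads = integer(), freq = numeric(),
      consensus = character())
    class(out) <- c("amplicon_variants", class(out))
    return(out)
  }
  keys <- accepted_event_keys(as.data.frame(accepted), region)
  ev <- aln$events[aln$events$read_id %in% rd$read_id]
  ev <- ev[ev$pos >= s & ev$pos <= e]
  ev[, key := paste(pos, ref, alt, sep = "|")]
  ev <- ev[key %in% keys]
  per_read <- ev[order(pos, ref, alt), .(sig = paste(key, collapse = ";")), by = read_id]
  sig <- stats::setNames(rep("", nrow(rd)), rd$read_id)
  sig[per_read$read_id] <- per_read$sig
  grp <- data.table::data.table(sig = as.character(sig))[, .N, by = sig]
  data.table::setorder(grp, -N, sig)
  # merge or drop under-supported variants
  if (any(grp$N < cfg$min_support) && nrow(grp) > 1L) {
    keep <- grp[N >= cfg$min_support]
    small <- grp[N < cfg$min_support]
    if (nrow(keep) == 0L) {
      keep <- grp[1L]; small <- grp[-1L]
    }
    if (cfg$merge_small && nrow(small)) {
      keysets <- lapply(strsplit(keep$sig, ";", fixed = TRUE), function(x) x[x != ""])
      for (i in seq_len(nrow(small))) {
        sm <- strsplit(small$sig[i], ";", fixed = TRUE)[[1L]]
        sm <- sm[sm != ""]
        dist <- vapply(keysets, function(ks)
          length(setdiff(ks, sm)) + length(setdiff(sm, ks)), 1L)
        j <- which.min(dist)
        keep$N[j] <- keep$N[j] + small$N[i]
      }
    }
    grp <- keep
  }
  # rescue insertion-lengthened reads that cannot span the full reference
  # interval: assign each to the unique variant consistent with its events
  if (any(rescue) && nrow(grp)) {
    restrict <- function(keyvec, lo, hi) {
      if (!length(keyvec)) return(character())
      parts <- strsplit(keyvec, "|", fixed = TRUE)
      pos_k <- vapply(parts, function(x) as.integer(x[1L]), 1L)
      ref_k <- vapply(parts, function(x) if (length(x) > 1L) x[2L] else "", "")
      end_k <- pos_k + pmax(nchar(ref_k), 1L) - 1L
      sort(keyvec[pos_k >= lo & end_k <= hi])
    }
    keysets <- lapply(strsplit(grp$sig, ";", fixed = TRUE), function(x) x[x != ""])
    rr <- rd_all[rescue]
    ev_r <- aln$events[aln$events$read_id %in% rr$read_id]
    ev_r <- ev_r[ev_r$pos >= s & ev_r$pos <= e]
    ev_r[, key := paste(pos, ref, alt, sep = "|")]
    ev_r <- ev_r[key %in% keys]
    for (i in seq_len(nrow(rr))) {
      lo <- pmax(rr$rp_start[i], s) + 5L
      hi <- pmin(rr$rp_end[i], e) - 5L
      if (hi <= lo) next
      rsig <- restrict(ev_r$key[ev_r$read_id == rr$read_id[i]], lo, hi)
      cand <- which(vapply(keysets, function(ks)
        identical(restrict(ks, lo, hi), rsig), TRUE))
      if (length(cand) == 1L) grp$N[cand] <- grp$N[cand] + 1L
    }
  }
  total <- sum(grp$N)
  data.table::setorder(grp, -N, sig)
  grp[, freq := 100 * N / total]
  refseg <- substr(region$sequence, s, e)
  grp[, consensus := vapply(sig, function(sg) {
    if (sg == "") return(refseg)
    parts <- strsplit(strsplit(sg, ";", fixed = TRUE)[[1L]], "|", fixed = TRUE)
    et <- edit_table(vapply(parts, function(x) as.integer(x[1L]), 1L) - s + 1L,
                     vapply(parts, function(x) if (length(x) > 1L) x[2L] else "", ""),
                     vapply(parts, function(x) if (length(x) > 2L) x[3L] else "", ""))
    apply_edits(refseg, et)
  }, "")]
  grp[, event_string := vapply(sig, function(sg) {
    if (sg == "") return("")
    parts <- strsplit(strsplit(sg, ";", fixed = TRUE)[[1L]], "|", fixed = TRUE)
    et <- edit_table(vapply(parts, function(x) as.integer(x[1L]), 1L),
                     vapply(parts, function(x) if (length(x) > 1L) x[2L] else "", ""),
                     vapply(parts, function(x) if (length(x) > 2L) x[3L] else "", ""))
    et[, pos := internal_to_rp(region, pos)]
    edits_to_string(et)
  }, "")]
  out <- grp[, .(variant_id = sprintf("%s.v%d", pair_name, seq_len(.N)),
                 pair_name = pair_name, event_string, n_reads = N, freq,
                 consensus)]
  class(out) <- c("amplicon_variants", class(out))
  out[]
}

# identity as matches / aligned columns from a global pairwise alignment
global_identity <- function(a, b, cfg = align_config()) {
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a), Biostrings::DNAString(b),
                                      type = "global",
                                      substitutionMatrix = subst_matrix(cfg),
                                      gapOpening = cfg$gap_open,
                                      gapExtension = cfg$gap_ext)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  c(identity = sum(p == s & p != "-") / length(p), score = Biostrings::score(pa))
}

#' Assign an amplicon variant to a panel allele
#'
#' Globally aligns the variant consensus against each panel entry (already
#' restricted to the homologous region) and returns the maximum-identity
#' entry; ties are broken by higher alignment score then lexicographic
#' allele name, and assignments separated from the runner-up by less than
#' `margin` identity percentage points are flagged ambiguous.
#'
#' @param consensus variant consensus sequence.
#' @param panel data.frame from [read_allele_panel()] (allele_name,
#'   genome_label, sequence).
#' @param margin ambiguity margin in identity percentage points.
#' @return list: allele_name, genome_label, identity_pct, ambiguous.
#' @export
assign_allele <- function(consensus, panel, margin = 1) {
  stopifnot(nrow(panel) >= 1L)
  res <- t(vapply(panel$sequence, function(s) global_identity(consensus, s),
                  c(identity = 0, score = 0)))
  id_pct <- 100 * res[, "identity"]
  ord <- order(-id_pct, -res[, "score"], panel$allele_name)
  best <- ord[1L]
  second <- if (length(ord) > 1L) id_pct[ord[2L]] else -Inf
  list(allele_name = panel$allele_name[best],
       genome_label = panel$genome_label[best],
       identity_pct = unname(id_pct[best]),
       ambiguous = unname(id_pct[best] - second) < margin)
}

#' Cross-library amplicon-variant frequency matrix
#'
#' Variants are matched across libraries by identical event string; a
#' variant absent from a library is 0%.
#'
#' @param variants_by_library named list of `amplicon_variants` tables (one
#'   amplicon each).
#' @return matrix (variant event string x library) of frequencies (%).
#' @export
frequency_table <- function(variants_by_library) {
  stopifnot(length(variants_by_library) >= 1L)
  sigs <- unique(unlist(lapply(variants_by_library, function(v) v$event_string)))
  sigs <- sigs[order(sigs != "", sigs)]  # reference-identical variant first
  m <- matrix(0, length(sigs), length(variants_by_library),
              dimnames = list(ifelse(sigs == "", "(reference)", sigs),
                              names(variants_by_library)))
  for (j in seq_along(variants_by_library)) {
    v <- variants_by_library[[j]]
    m[match(v$event_string, sigs), j] <- v$freq
  }
  m
}
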
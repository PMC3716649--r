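# Per-position SNP/indel calling with frequency thresholds and
# cross-library confirmation of rare variants.
#
# The primary rule: an event is called in a library when the position has
# sequencing depth >= min_depth (default 40) and the non-reference fraction
# is >= min_freq_pct (default 20%).  Events below either threshold remain
# candidates and can be rescued by the cross-library rule: present (freq >
# 0) in at least `rare_min_other_libraries` other libraries with at least
# `rare_min_pct_in_one` percent in one of them.  Indels are treated with
# the same thresholds as SNPs.

#' Variant-calling configuration
#'
#' @param min_depth minimum pileup depth for a direct call.
#' @param min_freq_pct minimum non-reference percentage for a direct call.
#' @param rare_min_other_libraries number of other libraries an unconfirmed
#'   candidate must appear in.
#' @param rare_min_pct_in_one minimum percentage required in at least one of
#'   those other libraries.
#' @export
call_config <- function(min_depth = 40L, min_freq_pct = 20,
                        rare_min_other_libraries = 2L, rare_min_pct_in_one = 5) {
  stopifnot(min_depth > 0L, min_freq_pct > 0, rare_min_other_libraries > 0L,
            rare_min_pct_in_one > 0)
  structure(list(min_depth = as.integer(min_depth),
                 min_freq_pct = min_freq_pct,
                 rare_min_other_libraries = as.integer(rare_min_other_libraries),
                 rare_min_pct_in_one = rare_min_pct_in_one),
            class = "call_config")
}

#' Call variants at a single pileup column
#'
#' @param counts named counts (A, C, G, T, N, del) or a one-row slice of
#'   `pileup$columns`; `depth` is taken as their sum.
#' @param ref_base the reference base at this position.
#' @param cfg a [call_config()].
#' @return data.table of SNP calls (alt base, count, freq, depth, status);
#'   N is never reported as an allele.
#' @export
call_column <- function(counts, ref_base, cfg = call_config()) {
  if (!ref_base %in% c("A", "C", "G", "T"))
    stop("ref_base must be one of A/C/G/T")
  cnt <- vapply(c("A", "C", "G", "T"), function(b)
    as.integer(counts[[b]] %||% 0L), 1L)
  depth <- if (!is.null(counts[["depth"]])) as.integer(counts[["depth"]])
           else sum(cnt) + as.integer(counts[["del"]] %||% 0L) +
                as.integer(counts[["N"]] %||% 0L)
  alts <- setdiff(names(cnt)[cnt > 0L], ref_base)
  if (length(alts) == 0L || depth == 0L)
    return(data.table::data.table(alt = character(), count = integer(),
                                  freq = numeric(), depth = integer(),
                                  status = character()))
  freq <- 100 * cnt[alts] / depth
  data.table::data.table(
    alt = alts, count = cnt[alts], freq = as.numeric(freq), depth = depth,
    status = ifelse(depth >= cfg$min_depth & freq >= cfg$min_freq_pct,
                    "called", "candidate"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call SNPs and indels across a library's pileup
#'
#' @param pile a `pileup` from [build_pileup()].
#' @param region the [reference_region()].
#' @param cfg a [call_config()].
#' @param library library name recorded on the result.
#' @return a `library_calls` object: list with `calls` (data.table: rp,
#'   type, ref, alt, count, freq, depth, status) and `coverage` (data.table:
#'   rp, depth).  Indel alts are written "+SEQ" / "-SEQ"; insertion depth is
#'   taken at the anchor column, deletion depth at the first deleted base.
#' @export
call_pileup <- function(pile, region, cfg = call_config(), library = "lib") {
  cols <- pile$columns
  refch <- strsplit(region$sequence, "", fixed = TRUE)[[1L]]
  out <- list()
  if (nrow(cols)) {
    base_cols <- c("A", "C", "G", "T")
    for (b in base_cols) {
      ref_b <- refch[cols$pos]
      sel <- which(cols[[b]] > 0L & ref_b != b)
      if (length(sel)) {
        freq <- 100 * cols[[b]][sel] / cols$depth[sel]
        out[[b]] <- data.table::data.table(
          pos = cols$pos[sel], type = "snp", ref = ref_b[sel], alt = b,
          count = cols[[b]][sel], freq = freq, depth = cols$depth[sel])
      }
    }
  }
  if (nrow(pile$indels)) {
    depth_at <- stats::setNames(cols$depth, cols$pos)
    ind <- data.table::copy(pile$indels)
    anchor <- ifelse(ind$type == "ins", ind$pos, ind$pos)
    d <- as.integer(depth_at[as.character(anchor)])
    d[is.na(d)] <- 0L
    out$indel <- data.table::data.table(
      pos = ind$pos, type = "indel",
      ref = ifelse(ind$type == "del", ind$seq, ""),
      alt = ifelse(ind$type == "ins", paste0("+", ind$seq), paste0("-", ind$seq)),
      count = ind$count, freq = ifelse(d > 0L, 100 * ind$count / d, NA_real_),
      depth = d)
  }
  calls <- data.table::rbindlist(out)
  if (nrow(calls) == 0L) {
    calls <- data.table::data.table(pos = integer(), type = character(),
      ref = character(), alt = character(), count = integer(),
      freq = numeric(), depth = integer())
  }
  calls[, rp := internal_to_rp(region, pos)]
  calls[, pos := NULL]
  calls[, status := ifelse(depth >= cfg$min_depth & freq >= cfg$min_freq_pct,
                           "called", "candidate")]
  data.table::setcolorder(calls, c("rp", "type", "ref", "alt", "count",
                                   "freq", "depth", "status"))
  data.table::setorder(calls, rp, type, alt)
  coverage <- data.table::data.table(rp = internal_to_rp(region, cols$pos),
                                     depth = cols$depth)
  structure(list(library = library, calls = calls[], coverage = coverage),
            class = "library_calls")
}

#' Cross-library confirmation of a rare candidate
#'
#' @param other_freqs frequencies (%) of the same (RP, type, alt) event in
#'   every other library (0 where the library covers the position without
#'   the event; exclude libraries without coverage).
#' @param cfg a [call_config()].
#' @return "cross_confirmed" or "rejected".
#' @export
confirm_rare <- function(other_freqs, cfg = call_config()) {
  if (length(other_freqs) < 2L)
    stop("cross-library rule undefined with fewer than 2 other libraries")
  present <- other_freqs[!is.na(other_freqs) & other_freqs > 0]
  if (length(present) >= cfg$rare_min_other_libraries &&
      any(present >= cfg$rare_min_pct_in_one)) "cross_confirmed" else "rejected"
}

#' Combine per-library call sets into one report
#'
#' One row per (RP, type, ref, alt) with per-library frequency, depth and
#' status; candidate events are passed through the cross-library rule when
#' at least three libraries are present.  Frequency is 0 where a library
#' covers the RP without the event and NA where it has no coverage.
#'
#' @param libs named list of `library_calls` objects.
#' @param cfg a [call_config()].
#' @return list with `table` (data.table, sorted by RP) and `summary`
#'   (positions_total, snp_positions, indel_positions, both_positions,
#'   counting events whose final status is called or cross_confirmed).
#' @export
combine_reports <- function(libs, cfg = call_config()) {
  stopifnot(length(libs) >= 1L)
  if (is.null(names(libs)) || any(names(libs) == ""))
    names(libs) <- vapply(libs, function(l) l$library, "")
  all_calls <- data.table::rbindlist(
    lapply(names(libs), function(nm) {
      d <- data.table::copy(libs[[nm]]$calls); d[, library := nm]; d
    }))
  key <- c("rp", "type", "ref", "alt")
  if (nrow(all_calls) == 0L) {
    return(list(table = data.table::data.table(rp = integer(), type = character(),
                ref = character(), alt = character()),
                summary = list(positions_total = 0L, snp_positions = 0L,
                               indel_positions = 0L, both_positions = 0L)))
  }
  events <- unique(all_calls[, ..key])
  data.table::setorderv(events, key)
  tbl <- data.table::copy(events)
  status_mat <- matrix(NA_character_, nrow(events), length(libs),
                       dimnames = list(NULL, names(libs)))
  freq_mat <- matrix(NA_real_, nrow(events), length(libs))
  for (j in seq_along(libs)) {
    nm <- names(libs)[j]
    m <- libs[[nm]]$calls[events, on = key]
    cov <- libs[[nm]]$coverage
    covered <- events$rp %in% cov$rp
    freq <- m$freq
    freq[is.na(freq) & covered] <- 0
    depth <- m$depth
    if (any(is.na(depth) & covered)) {
      dd <- stats::setNames(cov$depth, cov$rp)
      depth[is.na(depth) & covered] <- dd[as.character(events$rp[is.na(depth) & covered])]
    }
    st <- m$status
    st[is.na(st) & covered & freq == 0] <- NA_character_
    tbl[, (paste0("freq_", nm)) := freq]
    tbl[, (paste0("depth_", nm)) := depth]
    tbl[, (paste0("status_", nm)) := st]
    status_mat[, j] <- st
    freq_mat[, j] <- freq
  }
  # cross-library rescue of candidates
  if (length(libs) >= 3L) {
    for (i in seq_len(nrow(events))) {
      cand <- which(status_mat[i, ] == "candidate")
      for (j in cand) {
        others <- freq_mat[i, -j]
        others <- others[!is.na(others)]
        st <- if (length(others) >= 2L) confirm_rare(others, cfg) else "rejected"
        status_mat[i, j] <- st
        tbl[i, (paste0("status_", colnames(status_mat)[j])) := st]
      }
    }
  } else {
    status_mat[status_mat == "candidate"] <- "rejected"
    for (nm in names(libs))
      tbl[get(paste0("status_", nm)) == "candidate",
          (paste0("status_", nm)) := "rejected"]
  }
  accepted <- apply(status_mat, 1L, function(s)
    any(s %in% c("called", "cross_confirmed"), na.rm = TRUE))
  tbl[, accepted := accepted]
  acc <- events[accepted]
  rp_snp <- unique(acc$rp[acc$type == "snp"])
  rp_ind <- unique(acc$rp[acc$type == "indel"])
  summary <- list(
    positions_total = length(union(rp_snp, rp_ind)),
    snp_positions = length(setdiff(rp_snp, rp_ind)),
    indel_positions = length(setdiff(rp_ind, rp_snp)),
    both_positions = length(intersect(rp_snp, rp_ind)))
  list(table = tbl[], summary = summary)
}
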
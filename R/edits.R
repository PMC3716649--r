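# Edit lists: the internal representation of sequence differences.
#
# An edit table describes how a derived sequence differs from a parent
# sequence, in parent (1-based) coordinates:
#   snp  pos = substituted base,           nchar(ref) == nchar(alt) == 1
#   del  pos = first deleted base,         alt == ""
#   ins  pos = base AFTER which alt goes,  ref == ""   (anchored insertion)
# Edits must be sorted by pos and non-overlapping.  This single convention
# is used for homeolog divergence events, planted haplotype events and
# truth-set variants, so coordinates never drift between stages.

#' Construct an edit table
#'
#' @param pos integer vector of parent-sequence positions (1-based).
#' @param ref character vector of parent alleles ("" for insertions).
#' @param alt character vector of derived alleles ("" for deletions).
#' @return a `data.table` with columns `pos`, `ref`, `alt`, `type`.
#' @keywords internal
edit_table <- function(pos = integer(), ref = character(), alt = character()) {
  stopifnot(length(pos) == length(ref), length(pos) == length(alt))
  et <- data.table::data.table(pos = as.integer(pos),
                               ref = toupper(as.character(ref)),
                               alt = toupper(as.character(alt)))
  et[, type := ifelse(ref == "", "ins", ifelse(alt == "", "del", "snp"))]
  if (any(et$type == "snp" & (nchar(et$ref) != 1L | nchar(et$alt) != 1L)))
    stop("snp edits must have single-base ref and alt")
  if (any(et$ref == "" & et$alt == ""))
    stop("edit with empty ref and alt")
  # order by position; an insertion (anchored AFTER pos) sorts after a
  # substitution or deletion at the same pos
  et <- et[order(et$pos, et$type == "ins")]
  if (nrow(et) > 1L) {
    sp <- edit_span(et)
    if (any(sp$start[-1L] <= cummax(sp$end)[-nrow(et)]))
      stop("overlapping edits")
    if (anyDuplicated(et$pos[et$type == "ins"]))
      stop("overlapping edits (duplicate insertion anchor)")
  }
  et[]
}

empty_edits <- function() edit_table()

# ref span consumed by each edit (ins consumes none; span is [pos+1, pos])
edit_span <- function(et) {
  if (nrow(et) == 0L)
    return(data.table::data.table(start = integer(), end = integer()))
  data.table::data.table(
    start = ifelse(et$type == "ins", et$pos + 1L, et$pos),
    end   = et$pos + nchar(et$ref) - ifelse(et$type == "ins", 0L, 1L))
}

#' Check that an edit table's ref alleles match a parent sequence
#' @keywords internal
validate_edits <- function(et, seq) {
  if (nrow(et) == 0L) return(invisible(TRUE))
  n <- nchar(seq)
  sp <- edit_span(et)
  if (any(et$pos < ifelse(et$type == "ins", 0L, 1L)) || any(sp$end > n))
    stop("edit position outside sequence")
  obs <- substring(seq, sp$start, sp$end)
  bad <- which(et$type != "ins" & obs != et$ref)
  if (length(bad))
    stop(sprintf("ref mismatch at position %d: expected '%s', sequence has '%s'",
                 et$pos[bad[1L]], et$ref[bad[1L]], obs[bad[1L]]))
  invisible(TRUE)
}

#' Apply an edit table to a sequence
#' @keywords internal
apply_edits <- function(seq, et) {
  if (nrow(et) == 0L) return(seq)
  validate_edits(et, seq)
  # assemble unchanged chunks interleaved with alt alleles
  sp <- edit_span(et)
  pieces <- character(2L * nrow(et) + 1L)
  cur <- 1L
  for (i in seq_len(nrow(et))) {
    pieces[2L * i - 1L] <- if (sp$start[i] > cur) substr(seq, cur, sp$start[i] - 1L) else ""
    pieces[2L * i] <- et$alt[i]
    cur <- sp$end[i] + 1L
  }
  pieces[2L * nrow(et) + 1L] <- if (cur <= nchar(seq)) substr(seq, cur, nchar(seq)) else ""
  paste0(pieces, collapse = "")
}

#' Map parent-sequence positions into derived-sequence coordinates
#'
#' Positions falling inside a deleted span map to NA unless `side` is given:
#' `"left"` maps to the last kept base before the deletion, `"right"` to the
#' first kept base after it.
#' @keywords internal
map_ref_pos <- function(et, pos, side = c("na", "left", "right")) {
  side <- match.arg(side)
  pos <- as.integer(pos)
  if (nrow(et) == 0L) return(pos)
  sp <- edit_span(et)
  delta <- nchar(et$alt) - nchar(et$ref)
  out <- integer(length(pos))
  for (k in seq_along(pos)) {
    p <- pos[k]
    shift <- 0L
    hit <- NA_integer_
    for (i in seq_len(nrow(et))) {
      if (sp$end[i] < p && !(et$type[i] != "ins" && sp$start[i] <= p && p <= sp$end[i])) {
        if (sp$end[i] < p) shift <- shift + delta[i]
      }
      if (et$type[i] != "ins" && sp$start[i] <= p && p <= sp$end[i]) hit <- i
    }
    if (!is.na(hit)) {
      if (et$type[hit] == "snp") {
        out[k] <- p + shift
      } else if (side == "na") {
        out[k] <- NA_integer_
      } else if (side == "left") {
        out[k] <- sp$start[hit] - 1L + shift
      } else {
        out[k] <- sp$start[hit] + nchar(et$alt[hit]) + shift
      }
    } else {
      out[k] <- p + shift
    }
  }
  out
}

#' Map a parent-coordinate interval onto the derived sequence
#'
#' The returned interval covers everything the derived sequence retains of
#' the parent interval, including insertions anchored strictly inside it.
#' @keywords internal
map_ref_interval <- function(et, start, end) {
  s <- map_ref_pos(et, start, side = "right")
  e <- map_ref_pos(et, end, side = "left")
  c(s, e)
}

#' Invert an edit table
#'
#' Re-expresses parent->derived edits as derived->parent edits in derived
#' coordinates (ref and alt swap roles).
#' @keywords internal
invert_edits <- function(et) {
  if (nrow(et) == 0L) return(empty_edits())
  pos2 <- integer(nrow(et)); ref2 <- character(nrow(et)); alt2 <- character(nrow(et))
  shift <- 0L
  for (i in seq_len(nrow(et))) {
    if (et$type[i] == "snp") {
      pos2[i] <- et$pos[i] + shift; ref2[i] <- et$alt[i]; alt2[i] <- et$ref[i]
    } else if (et$type[i] == "del") {
      # bases absent from derived: insertion after the base preceding them
      pos2[i] <- et$pos[i] - 1L + shift; ref2[i] <- ""; alt2[i] <- et$ref[i]
    } else {
      # inserted bases present in derived: delete them there
      pos2[i] <- et$pos[i] + 1L + shift; ref2[i] <- et$alt[i]; alt2[i] <- ""
    }
    shift <- shift + nchar(et$alt[i]) - nchar(et$ref[i])
  }
  edit_table(pos2, ref2, alt2)
}

#' Compose two disjoint edit tables
#'
#' `et_a` and `et_b` are both expressed against the same parent sequence and
#' must touch disjoint spans; returns the differences of sequence A relative
#' to sequence B, in B's coordinates.  Used to express homeolog backbones
#' against the single pipeline reference.
#' @keywords internal
diff_against <- function(et_a, et_b) {
  if (nrow(et_a) && nrow(et_b)) {
    sp_a <- edit_span(et_a); sp_b <- edit_span(et_b)
    for (i in seq_len(nrow(et_a)))
      if (any(pmax(sp_a$start[i], sp_b$start) <= pmin(sp_a$end[i], sp_b$end) &
              !(et_a$type[i] == "ins" & et_b$type == "ins")))
        stop("edit tables overlap; cannot compose")
  }
  inv_b <- invert_edits(et_b)       # B coords: B -> parent
  if (nrow(et_a) == 0L) return(inv_b)
  # re-anchor A's parent-coordinate edits into B coordinates
  pos_b <- map_ref_pos(et_b, et_a$pos, side = "left")
  moved <- edit_table(pos_b, et_a$ref, et_a$alt)
  combined <- rbind(inv_b, moved)
  edit_table(combined$pos, combined$ref, combined$alt)
}

#' Left-align indel edits against their parent sequence
#'
#' Standard indel normalisation: an indel inside a repeat run is shifted to
#' the leftmost equivalent position so that one event maps to one reference
#' position.  SNPs are untouched.
#' @keywords internal
normalize_edits <- function(et, seq) {
  if (nrow(et) == 0L) return(et)
  pos <- et$pos; ref <- et$ref; alt <- et$alt
  for (i in seq_len(nrow(et))) {
    if (et$type[i] == "del") {
      len <- nchar(ref[i])
      while (pos[i] > 1L &&
             substr(seq, pos[i] - 1L, pos[i] - 1L) == substr(ref[i], len, len)) {
        pos[i] <- pos[i] - 1L
        ref[i] <- substr(seq, pos[i], pos[i] + len - 1L)
      }
    } else if (et$type[i] == "ins") {
      len <- nchar(alt[i])
      while (pos[i] >= 1L &&
             substr(seq, pos[i], pos[i]) == substr(alt[i], len, len)) {
        alt[i] <- paste0(substr(seq, pos[i], pos[i]), substr(alt[i], 1L, len - 1L))
        pos[i] <- pos[i] - 1L
      }
    }
  }
  edit_table(pos, ref, alt)
}

#' Render edits as a compact event string ("293C>T; 491delTCC; 829insGT...")
#' @keywords internal
edits_to_string <- function(et) {
  if (nrow(et) == 0L) return("")
  lab <- ifelse(et$type == "snp", paste0(et$pos, et$ref, ">", et$alt),
         ifelse(et$type == "del", paste0(et$pos, "del", et$ref),
                paste0(et$pos, "ins", et$alt)))
  paste(lab, collapse = ";")
}

#' Parse the event-string rendering back into an edit table
#' @keywords internal
parse_edit_string <- function(s) {
  if (is.na(s) || s == "") return(empty_edits())
  toks <- strsplit(s, ";", fixed = TRUE)[[1L]]
  m <- regmatches(toks, regexec("^([0-9]+)(?:([ACGTN])>([ACGTN])|del([ACGTN]+)|ins([ACGTN]+))$", toks))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop("unparseable event token: ", toks[bad][1L])
  pos <- vapply(m, function(x) as.integer(x[2L]), 1L)
  ref <- vapply(m, function(x) if (x[3L] != "") x[3L] else x[5L], "")
  alt <- vapply(m, function(x) if (x[4L] != "") x[4L] else x[6L], "")
  edit_table(pos, ref, alt)
}
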
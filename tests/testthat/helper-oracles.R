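# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written against the contracts, not the package internals:
# exhaustive searches and textbook dynamic programming at small n.

# exhaustive modified-Mott trim: best-scoring contiguous window by direct
# O(n^2) search, ties to smallest start then largest end, then the same
# terminal ambiguity rule and minimum length
oracle_trim <- function(seq, qual, limit = 0.05, max_ambiguous = 4L,
                        min_length = 50L) {
  q <- utf8ToInt(qual) - 33L
  sc <- limit - 10^(-q / 10)
  n <- length(sc)
  best <- 0; bs <- NA_integer_; be <- NA_integer_
  for (i in seq_len(n)) {
    acc <- 0
    for (j in i:n) {
      acc <- acc + sc[j]
      if (acc > best + 1e-12) {
        best <- acc; bs <- i; be <- j
      } else if (!is.na(bs) && abs(acc - best) <= 1e-12 &&
                 (i < bs || (i == bs && j > be))) {
        bs <- i; be <- j
      }
    }
  }
  if (is.na(bs) || best <= 1e-12) return(NULL)
  s <- substr(seq, bs, be)
  ch <- strsplit(s, "")[[1L]]
  lead <- 0L; while (lead < length(ch) && ch[lead + 1L] == "N") lead <- lead + 1L
  trail <- 0L; while (trail < length(ch) - lead && ch[length(ch) - trail] == "N") trail <- trail + 1L
  lo <- 1L; hi <- length(ch)
  if (lead > max_ambiguous) lo <- lead + 1L
  if (trail > max_ambiguous) hi <- length(ch) - trail
  if (hi - lo + 1L < min_length) return(NULL)
  c(start = bs + lo - 1L, end = bs + hi - 1L)
}

# textbook affine-gap semi-global DP (pattern global, subject free ends);
# gap of length L costs open + L * ext; returns the optimal score
oracle_align_score <- function(read, ref, match = 1, mismatch = -2,
                               gap_open = 4, gap_ext = 1) {
  p <- strsplit(read, "")[[1L]]; s <- strsplit(ref, "")[[1L]]
  n <- length(p); m <- length(s)
  NEG <- -1e9
  # rows: read positions 0..n ; free leading/trailing subject
  M <- matrix(NEG, n + 1L, m + 1L)   # read i aligned ending in match/mismatch state
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in subject (read base insertion)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in read (subject base deletion)
  M[1L, ] <- 0                        # start anywhere in subject for free
  for (i in 2L:(n + 1L)) {
    X[i, 1L] <- max(M[i - 1L, 1L] - gap_open - gap_ext, X[i - 1L, 1L] - gap_ext)
    for (j in 2L:(m + 1L)) {
      sc <- if (p[i - 1L] == s[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L]) + sc
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_ext, X[i - 1L, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_ext, Y[i, j - 1L] - gap_ext)
    }
  }
  max(M[n + 1L, ], X[n + 1L, ])      # free trailing subject: max over j
}

# exhaustive intron-candidate enumeration against the stated conditions,
# using Biostrings translation as the independent stop check
oracle_scan_intervals <- function(consensus, net, skip, max_len) {
  n <- nchar(consensus)
  out <- list()
  for (L in 4:min(max_len, n - 1L)) {
    if ((net - L) %% 3L != 0L) next
    for (i in seq_len(n - L + 1L)) {
      spliced <- paste0(substr(consensus, 1L, i - 1L),
                        substr(consensus, i + L, n))
      body <- substr(spliced, skip + 1L, nchar(spliced))
      nb <- nchar(body) - nchar(body) %% 3L
      if (nb >= 6L) {
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAString(substr(body, 1L, nb))))
        if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))) next
      }
      out[[length(out) + 1L]] <- c(start = i, end = i + L - 1L)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  as.data.frame(do.call(rbind, out))
}

# events fully inside the primer-safe interior of some amplicon: primer
# synthesis overwrites template variation at product ends, so events whose
# span touches a primer zone (plus slack for left-alignment) are not
# recoverable from reads and are excluded from truth comparisons
interior_events <- function(d, amps, margin = 26L) {
  span_end <- d$rp + ifelse(d$type == "snp", 0L,
                            pmax(nchar(sub("^[+-]", "", d$alt)) - 1L, 0L))
  ok <- rep(FALSE, nrow(d))
  for (k in seq_len(nrow(amps)))
    ok <- ok | (d$rp >= amps$rp_start[k] + margin &
                span_end <= amps$rp_end[k] - margin)
  ok
}

# Event-table comparison up to alignment equivalence.  Clustered events
# can have several equal-score decompositions (e.g. delT@922 + G>A@924 vs
# T>A@922 + delG@924); two reports agree when every cluster of differing
# keys yields the same local sequence once each side's events are applied
# to the reference.
check_event_equivalence <- function(truth, acc, region, gap = 20L) {
  key <- function(x) paste(x$rp, x$type, x$ref, x$alt)
  only_t <- truth[!key(truth) %in% key(acc), , drop = FALSE]
  only_a <- acc[!key(acc) %in% key(truth), , drop = FALSE]
  if (!nrow(only_t) && !nrow(only_a)) return(TRUE)
  to_edits <- function(d) {
    ref <- ifelse(d$type == "snp", d$ref,
           ifelse(startsWith(d$alt, "-"), sub("^-", "", d$alt), ""))
    alt <- ifelse(d$type == "snp", d$alt,
           ifelse(startsWith(d$alt, "+"), sub("^\\+", "", d$alt), ""))
    data.frame(pos = d$rp - region$rp_offset, ref = ref, alt = alt)
  }
  allpos <- sort(unique(c(only_t$rp, only_a$rp)))
  cl <- cumsum(c(1L, diff(allpos) > gap))
  for (g in unique(cl)) {
    ps <- allpos[cl == g]
    lo <- min(ps) - 10L; hi <- max(ps) + 10L
    apply_side <- function(d) {
      w <- d[d$rp >= lo & d$rp <= hi, , drop = FALSE]
      et <- to_edits(w)
      tryCatch(polyamp:::apply_edits(
        substr(region$sequence, lo - region$rp_offset, hi - region$rp_offset),
        polyamp:::edit_table(et$pos - (lo - region$rp_offset) + 1L, et$ref, et$alt)),
        error = function(e) NA_character_)
    }
    s_t <- apply_side(truth); s_a <- apply_side(acc)
    if (is.na(s_t) || is.na(s_a) || !identical(s_t, s_a)) return(FALSE)
  }
  TRUE
}

rand_read <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rand_quals <- function(n, lo = 2L, hi = 40L)
  intToUtf8(sample(lo:hi, n, TRUE) + 33L)

# small shared simulation fixture, built once per test run
.fixture_env <- new.env(parent = emptyenv())
small_sim <- function(depth = 250L, seed = 42L) {
  key <- sprintf("sim_%d_%d", depth, seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_pool(seed = seed, n_libraries = 3L,
                                         depth = depth,
                                         em = error_model(0, 0))
  .fixture_env[[key]]
}
small_pipeline <- function(depth = 250L, seed = 42L) {
  key <- sprintf("pipe_%d_%d", depth, seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- small_sim(depth, seed)
    .fixture_env[[key]] <- run_pipeline(sim$libraries, sim$region,
                                        sim$amplicons, panel = sim$panel)
  }
  .fixture_env[[key]]
}
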
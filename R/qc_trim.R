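# Quality and ambiguity trimming of raw amplicon reads.
#
# The trimmer is the standard limit-based (modified-Mott) algorithm: each
# base scores (limit - p_err) with p_err = 10^(-Q/10); the kept segment is
# the contiguous window with the maximal score sum.  A limit of 0.05 leaves
# high-quality (Q >= 20) long-read libraries essentially untouched, which is
# the behaviour expected of pooled 454 amplicon data.

#' Trimming configuration
#'
#' @param limit error-probability limit for the modified-Mott trim; bases
#'   with error probability above `limit` score negatively.
#' @param max_ambiguous maximum number of ambiguous bases (N) tolerated in a
#'   terminal run at either read end; longer terminal N runs are cut off.
#' @param min_length reads shorter than this after trimming are rejected.
#' @export
trim_config <- function(limit = 0.05, max_ambiguous = 4L, min_length = 50L) {
  stopifnot(limit > 0, limit < 1, max_ambiguous >= 0L, min_length >= 1L)
  structure(list(limit = limit, max_ambiguous = as.integer(max_ambiguous),
                 min_length = as.integer(min_length)),
            class = "trim_config")
}

# maximal-sum contiguous window of the Mott scores; ties broken by smallest
# start, then largest end.  Returns c(start, end) or NULL if no positive sum.
mott_window <- function(score) {
  n <- length(score)
  p <- c(0, cumsum(score))                  # p[j+1] = sum of first j scores
  runmin <- cummin(p[-length(p)])           # min over prefixes 0..j-1
  gain <- p[-1L] - runmin                   # best window ending at j
  m <- max(gain)
  if (m <= 0) return(NULL)
  js <- which(gain >= m - 1e-12)
  # for each candidate end, the earliest start achieving the min prefix
  is <- vapply(js, function(j) which(p[seq_len(j)] <= runmin[j] + 1e-12)[1L], 1L)
  best <- order(is, -js)[1L]
  c(is[best], js[best])                     # start index (1-based), end index
}

# cut a terminal N run longer than max_ambiguous from each end
strip_ambiguous <- function(seq, max_ambiguous) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  lead <- 0L
  while (lead < n && ch[lead + 1L] == "N") lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && ch[n - trail] == "N") trail <- trail + 1L
  s <- 1L; e <- n
  if (lead > max_ambiguous) s <- lead + 1L
  if (trail > max_ambiguous) e <- n - trail
  if (s > e) return(c(1L, 0L))
  c(s, e)
}

#' Quality-trim a single read
#'
#' Returns the kept subread, or NULL if the read is rejected (no positive
#' quality window, or shorter than `min_length` after trimming).
#'
#' @param read single-record [fastq_set] (or list with seq/qual/id).
#' @param cfg a [trim_config()].
#' @return a single-record [fastq_set], or NULL.
#' @export
trim_read <- function(read, cfg = trim_config()) {
  q <- phred_scores(read$qual[1L])
  score <- cfg$limit - 10^(-q / 10)
  w <- mott_window(score)
  if (is.null(w)) return(NULL)
  seq <- substr(read$seq[1L], w[1L], w[2L])
  se <- strip_ambiguous(seq, cfg$max_ambiguous)
  if (se[2L] < se[1L]) return(NULL)
  s <- w[1L] + se[1L] - 1L
  e <- w[1L] + se[2L] - 1L
  if (e - s + 1L < cfg$min_length) return(NULL)
  fastq_set(read$id[1L], substr(read$seq[1L], s, e), substr(read$qual[1L], s, e))
}

#' Quality-trim a read library
#'
#' @param reads a [fastq_set].
#' @param cfg a [trim_config()].
#' @return list with `reads` (kept, trimmed) and `summary` (one-row
#'   data.frame: reads/mean length before and after, kept count).
#' @export
trim_library <- function(reads, cfg = trim_config()) {
  n0 <- length(reads)
  mean0 <- if (n0) mean(nchar(reads$seq)) else NA_real_
  kept <- vector("list", n0)
  for (i in seq_len(n0)) kept[[i]] <- trim_read(reads[i], cfg)
  keep <- !vapply(kept, is.null, TRUE)
  kept <- kept[keep]
  out <- if (length(kept)) {
    fastq_set(vapply(kept, function(r) r$id, ""),
              vapply(kept, function(r) r$seq, ""),
              vapply(kept, function(r) r$qual, ""))
  } else fastq_set()
  summary <- data.frame(
    reads_before = n0, mean_length_before = mean0,
    reads_after = length(out),
    mean_length_after = if (length(out)) mean(nchar(out$seq)) else NA_real_)
  list(reads = out, summary = summary)
}
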
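mk_region <- function(seq) reference_region("ref", seq)

perfect_reads <- function(region, starts, len, ids = NULL) {
  seqs <- substring(region$sequence, starts, starts + len - 1L)
  fastq_set(ids %||% paste0("r", seq_along(starts)), seqs,
            vapply(nchar(seqs), function(n) phred_string(rep(40, n)), ""))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a read equal to a reference substring aligns all-match", {
  set.seed(3)
  region <- mk_region(rand_read(300))
  aln <- align_reads(perfect_reads(region, 50, 120), region)
  expect_true(aln$reads$aligned)
  expect_equal(aln$reads$rp_start, 50L)
  expect_equal(aln$reads$rp_end, 169L)
  expect_equal(aln$reads$identity, 1)
  expect_equal(nrow(aln$events), 0L)
  expect_equal(reconstruct_read(aln, "r1", region), substr(region$sequence, 50, 169))
})

test_that("a single substitution yields one mismatch event at the planted RP", {
  set.seed(4)
  region <- mk_region(rand_read(300))
  seq <- substr(region$sequence, 40, 180)
  b <- substr(seq, 61, 61)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  substr(seq, 61, 61) <- alt
  aln <- align_reads(fastq_set("r1", seq, phred_string(rep(40, nchar(seq)))), region)
  expect_equal(nrow(aln$events), 1L)
  expect_equal(aln$events$pos, 40L + 60L)
  expect_equal(aln$events$alt, alt)
  expect_equal(aln$events$type, "snp")
})

test_that("reverse-complement reads are recognised and projected to plus", {
  set.seed(5)
  region <- mk_region(rand_read(300))
  plus <- substr(region$sequence, 30, 170)
  aln <- align_reads(fastq_set("r1", polyamp:::revcomp(plus),
                               phred_string(rep(40, nchar(plus)))), region)
  expect_equal(aln$reads$strand, "-")
  expect_equal(aln$reads$rp_start, 30L)
  expect_equal(aln$reads$identity, 1)
})

test_that("a deletion inside a homopolymer run is left-aligned", {
  # reference carries AAAA at 61..64; the read drops one A
  set.seed(6)
  left <- rand_read(60); right <- rand_read(60)
  region <- mk_region(paste0(left, "AAAA", right))
  read <- paste0(substr(left, 21, 60), "AAA", substr(right, 1, 40))
  aln <- align_reads(fastq_set("r1", read, phred_string(rep(40, nchar(read)))), region)
  ev <- aln$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "del")
  expect_equal(ev$pos, 61L)   # leftmost A of the run
})

test_that("multiple indels in one read keep their reference anchors", {
  set.seed(71)
  region <- mk_region(rand_read(400))
  ref <- region$sequence
  seg <- paste0("GT", rand_read(68), "AG")
  # 72-nt insertion after 120, 4-nt deletion of 200..203, 3-nt insertion
  # after 300: the classic multi-gap read
  read <- paste0(substr(ref, 50, 120), seg, substr(ref, 121, 199),
                 substr(ref, 204, 300), "TCA", substr(ref, 301, 350))
  aln <- align_reads(fastq_set("r1", read, phred_string(rep(40, nchar(read)))),
                     region, align_config(min_identity = 0.5))
  ev <- aln$events[order(aln$events$pos)]
  expect_equal(ev$type, c("ins", "del", "ins"))
  expect_equal(nchar(ev$alt), c(72L, 0L, 3L))
  # anchors equal the planted positions up to left-alignment slack
  expect_lte(abs(ev$pos[1] - 120L), 4L)
  expect_lte(abs(ev$pos[2] - 200L), 4L)
  expect_lte(abs(ev$pos[3] - 300L), 4L)
  # and the record reconstructs the read exactly
  expect_equal(reconstruct_read(aln, "r1", region), read)
})

test_that("alignment scores match the brute-force affine DP oracle", {
  set.seed(21)
  cfg <- align_config()
  region <- mk_region(rand_read(160))
  for (i in 1:40) {
    len <- sample(30:60, 1)
    start <- sample(1:(160 - len), 1)
    read <- substr(region$sequence, start, start + len - 1L)
    # corrupt with up to 3 substitutions and possibly a 1-2 nt indel
    ch <- strsplit(read, "")[[1L]]
    for (k in sample(seq_len(len), sample(0:3, 1)))
      ch[k] <- sample(setdiff(c("A", "C", "G", "T"), ch[k]), 1)
    read <- paste(ch, collapse = "")
    if (runif(1) < 0.5) {
      p <- sample(5:(len - 5), 1)
      read <- if (runif(1) < 0.5)
        paste0(substr(read, 1, p), substr(read, p + 2, len))
      else paste0(substr(read, 1, p), rand_read(2), substr(read, p + 1, len))
    }
    aln <- align_reads(fastq_set("r", read, phred_string(rep(40, nchar(read)))),
                       region, cfg)
    expect_equal(aln$reads$score,
                 oracle_align_score(read, region$sequence, cfg$match,
                                    cfg$mismatch, cfg$gap_open, cfg$gap_ext))
  }
})

test_that("pileup columns conserve counts and report events", {
  set.seed(8)
  region <- mk_region(rand_read(200))
  # one perfect read covering 10..49 -> 40 columns of depth 1
  aln <- align_reads(perfect_reads(region, 10, 40), region)
  pile <- build_pileup(aln, region)
  expect_equal(nrow(pile$columns), 40L)
  expect_true(all(pile$columns$depth == 1L))
  # two reads, one with C->T at RP 100
  r1 <- substr(region$sequence, 60, 140)
  r2 <- r1
  ref_b <- substr(region$sequence, 100, 100)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  substr(r2, 41, 41) <- alt_b
  aln2 <- align_reads(fastq_set(c("a", "b"), c(r1, r2),
                                rep(phred_string(rep(40, 81)), 2)), region)
  pile2 <- build_pileup(aln2, region)
  col <- pile2$columns[pile2$columns$pos == 100L, ]
  expect_equal(col$depth, 2L)
  expect_equal(col[[ref_b]], 1L)
  expect_equal(col[[alt_b]], 1L)
  # conservation: sum of depths = sum of reference-consuming bases
  rd <- aln2$reads
  expect_equal(sum(pile2$columns$depth), sum(rd$rp_end - rd$rp_start + 1L))
})

test_that("primer-end bases are masked out of pileup counts", {
  set.seed(9)
  region <- mk_region(rand_read(300))
  amp <- amplicon_set("P1",
                      substr(region$sequence, 41, 60),
                      polyamp:::revcomp(substr(region$sequence, 221, 240)),
                      41L, 240L)
  # read anchored at the forward primer with a variant inside the primer
  # zone (far enough from the terminus not to trigger end clipping)
  read <- substr(region$sequence, 41, 240)
  b <- substr(read, 15, 15)
  substr(read, 15, 15) <- setdiff(c("A", "C", "G", "T"), b)[1]
  aln <- align_reads(fastq_set("r1", read, phred_string(rep(40, nchar(read)))),
                     region, align_config(min_identity = 0.5))
  pile <- build_pileup(aln, region, amplicons = amp)
  expect_false(55L %in% pile$columns$pos)      # primer zone masked
  expect_true(70L %in% pile$columns$pos)       # interior kept
  pile_un <- build_pileup(aln, region)
  expect_true(55L %in% pile_un$columns$pos)    # unmasked without amplicons
})

test_that("zero-coverage positions are omitted and empty input handled", {
  region <- mk_region(rand_read(100))
  aln <- align_reads(fastq_set(), region)
  pile <- build_pileup(aln, region)
  expect_equal(nrow(pile$columns), 0L)
  expect_equal(nrow(pile$indels), 0L)
})
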
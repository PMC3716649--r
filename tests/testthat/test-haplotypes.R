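test_that("all-reference reads give one variant at 100%", {
  set.seed(14)
  region <- reference_region("r", rand_read(300))
  reads <- fastq_set(paste0("r", 1:20),
                     rep(substr(region$sequence, 21, 280), 20),
                     rep(phred_string(rep(40, 260)), 20))
  aln <- align_reads(reads, region)
  acc <- data.frame(rp = integer(), type = character(), ref = character(),
                    alt = character())
  v <- group_reads(aln, region, 21L, 280L, acc, pair_name = "P")
  expect_equal(nrow(v), 1L)
  expect_equal(v$event_string, "")
  expect_equal(v$freq, 100)
  expect_equal(v$consensus, substr(region$sequence, 21, 280))
})

test_that("zero-error mixtures are recovered at their frequencies", {
  sim <- small_sim()
  pipe <- small_pipeline()
  for (pn in names(pipe$variants)) {
    fmat <- pipe$variants[[pn]]$frequencies
    expect_equal(nrow(fmat), 3L)              # three haplotypes per amplicon
    for (lib in colnames(fmat)) {
      expect_equal(sum(fmat[, lib]), 100, tolerance = 1e-6)
      # 60/30/10 within 3 binomial SE of the full-span read total
      per <- pipe$variants[[pn]]$per_library[[lib]]
      n <- sum(per$n_reads)
      for (truth in c(60, 30, 10)) {
        se <- 100 * sqrt(truth / 100 * (1 - truth / 100) / n)
        expect_true(any(abs(fmat[, lib] - truth) <= 3 * se),
                    info = sprintf("%s %s truth %g", pn, lib, truth))
      }
    }
  }
})

test_that("recovered event strings match the planted edit lists", {
  sim <- small_sim()
  pipe <- small_pipeline()
  region <- sim$region
  for (pn in names(pipe$variants)) {
    k <- which(sim$amplicons$pair_name == pn)
    s <- sim$amplicons$rp_start[k] + 26L      # primer-safe interior
    e <- sim$amplicons$rp_end[k] - 26L
    # comparison is at the sequence level: equal-score decompositions of
    # clustered events are alignment-equivalent representations
    seq_of <- function(str) {
      et <- polyamp:::parse_edit_string(str)
      keep <- et$pos >= s & (et$pos + pmax(nchar(et$ref) - 1L, 0L)) <= e
      polyamp:::apply_edits(region$sequence, et[keep])
    }
    v1 <- pipe$variants[[pn]]$per_library[[1L]]
    got <- sort(unname(vapply(v1$event_string, seq_of, "")))
    want <- sort(unname(vapply(sim$hapset$haps, function(h)
      seq_of(polyamp:::edits_to_string(h$edits_vs_ref)), "")))
    expect_equal(got, want)
  }
})

test_that("under-supported variants merge into their nearest neighbour", {
  set.seed(15)
  region <- reference_region("r", rand_read(200))
  base <- substr(region$sequence, 11, 190)
  alt <- base
  b <- substr(alt, 50, 50)
  nb <- setdiff(c("A", "C", "G", "T"), b)[1]
  substr(alt, 50, 50) <- nb
  # 20 reference reads, 1 lone variant read (sequencing error analogue)
  reads <- fastq_set(paste0("r", 1:21), c(rep(base, 20), alt),
                     rep(phred_string(rep(40, 180)), 21))
  aln <- align_reads(reads, region)
  acc <- data.frame(rp = 60L, type = "snp", ref = b, alt = nb)
  v <- group_reads(aln, region, 11L, 190L, acc, hap_config(min_support = 2L),
                   pair_name = "P")
  expect_equal(nrow(v), 1L)
  expect_equal(v$n_reads, 21L)
  # with merging disabled the singleton is dropped
  v2 <- group_reads(aln, region, 11L, 190L, acc,
                    hap_config(min_support = 2L, merge_small = FALSE), "P")
  expect_equal(nrow(v2), 1L)
  expect_equal(v2$n_reads, 20L)
})

test_that("minor variants with enough support are retained", {
  # 0.1%-scale variants survive when backed by >= min_support reads
  set.seed(16)
  region <- reference_region("r", rand_read(200))
  base <- substr(region$sequence, 11, 190)
  alt <- base
  b <- substr(alt, 50, 50); nb <- setdiff(c("A", "C", "G", "T"), b)[1]
  substr(alt, 50, 50) <- nb
  reads <- fastq_set(paste0("r", 1:102), c(rep(base, 100), alt, alt),
                     rep(phred_string(rep(40, 180)), 102))
  aln <- align_reads(reads, region)
  acc <- data.frame(rp = 60L, type = "snp", ref = b, alt = nb)
  v <- group_reads(aln, region, 11L, 190L, acc, pair_name = "P")
  expect_equal(nrow(v), 2L)
  expect_equal(min(v$n_reads), 2L)
})

test_that("assign_allele picks the max-identity entry with tie handling", {
  set.seed(17)
  seqs <- rand_read(250)
  panel <- data.frame(allele_name = c("B1a", "A1a"), genome_label = c("B", "A"),
                      sequence = c(seqs, seqs), stringsAsFactors = FALSE)
  a <- assign_allele(seqs, panel)
  expect_equal(a$allele_name, "A1a")            # lexicographic on exact tie
  expect_true(a$ambiguous)
  expect_equal(a$identity_pct, 100)
  # 97% vs <=92%: correct genome, unambiguous
  near <- strsplit(seqs, "")[[1L]]
  far <- near
  for (k in sample(250, 8)) near[k] <- setdiff(c("A","C","G","T"), near[k])[1]
  for (k in sample(250, 25)) far[k] <- setdiff(c("A","C","G","T"), far[k])[1]
  panel2 <- data.frame(allele_name = c("trueA", "otherD"),
                       genome_label = c("A", "D"),
                       sequence = c(paste(near, collapse = ""),
                                    paste(far, collapse = "")))
  a2 <- assign_allele(seqs, panel2)
  expect_equal(a2$genome_label, "A")
  expect_false(a2$ambiguous)
  expect_gt(a2$identity_pct, 95)
})

test_that("frequency_table matches variants across libraries", {
  v1 <- data.table::data.table(variant_id = c("P.v1", "P.v2"), pair_name = "P",
                               event_string = c("", "10A>G"),
                               n_reads = c(60L, 40L), freq = c(60, 40),
                               consensus = c("x", "y"))
  v2 <- data.table::data.table(variant_id = "P.v1", pair_name = "P",
                               event_string = "", n_reads = 100L, freq = 100,
                               consensus = "x")
  m <- frequency_table(list(l1 = v1, l2 = v2))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["10A>G", "l2"], 0)             # absent variant -> 0%
  expect_equal(unname(colSums(m)), c(100, 100))
  single <- frequency_table(list(only = v2))
  expect_equal(unname(single[1, 1]), 100)
})
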
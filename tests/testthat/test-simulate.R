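test_that("make_panel is deterministic and honours zero divergence", {
  p1 <- make_panel(123, length = 600, divergence = 0.04, cds_start = 60)
  p2 <- make_panel(123, length = 600, divergence = 0.04, cds_start = 60)
  expect_identical(p1, p2)
  p0 <- make_panel(9, length = 600, divergence = 0, cds_start = 60)
  expect_equal(p0$genomes$A$seq, p0$genomes$B$seq)
  expect_equal(p0$genomes$B$seq, p0$genomes$D$seq)
  expect_error(make_panel(1, length = 600, divergence = 0.3), "divergence")
  expect_error(make_panel(1, length = 200), "length")
})

test_that("backbones are stop-free, ATG-anchored, and length-bounded", {
  p <- make_panel(77, length = 1200, divergence = 0.05, cds_start = 104)
  lens <- vapply(p$genomes, function(g) nchar(g$seq), 1L)
  expect_lte(max(lens) - min(lens), 30L)
  for (g in p$genomes) {
    expect_equal(substr(g$seq, g$cds_start, g$cds_start + 2L), "ATG")
    expect_false(polyamp:::cds_has_stop(g$seq, g$cds_start))
  }
})

test_that("divergence 0.05 gives ~0.95 mean pairwise identity (adist oracle)", {
  p <- make_panel(5, length = 1902, divergence = 0.05)
  pairs <- combn(c("A", "B", "D"), 2)
  ids <- apply(pairs, 2, function(pr) {
    a <- p$genomes[[pr[1]]]$seq; b <- p$genomes[[pr[2]]]$seq
    1 - utils::adist(a, b)[1, 1] / max(nchar(a), nchar(b))
  })
  expect_equal(mean(ids), 0.95, tolerance = 0.011)
  expect_true(mean(ids) > 0.93 && mean(ids) < 0.98)
})

test_that("plant_variants validates and composes against the reference", {
  p <- make_panel(31, length = 900, divergence = 0.04, cds_start = 104)
  region <- panel_reference(p)
  # empty specs -> the three backbones at 1/3 each
  hs <- plant_variants(p)
  expect_equal(length(hs$haps), 3L)
  expect_equal(sum(vapply(hs$haps, function(h) h$freq, 1)), 1)
  expect_equal(hs$haps[[2]]$seq, p$genomes$B$seq)
  # frequency sum validation
  expect_error(plant_variants(p, list(
    list(label = "x", genome = "B", freq = 0.6, events = NULL))), "sum")
  # ref mismatch at an event position -> truth error
  b <- substr(p$genomes$B$seq, 300, 300)
  wrong <- setdiff(c("A", "C", "G", "T"), b)[1]
  expect_error(plant_variants(p, list(
    list(label = "x", genome = "B", freq = 1,
         events = data.frame(pos = 300, ref = wrong, alt = b)))), "mismatch")
})

test_that("a planted stop truncates the truth protein where expected", {
  p <- make_panel(32, length = 900, divergence = 0, cds_start = 104)
  region <- panel_reference(p)
  # find a codon with a one-substitution stop
  refseq <- region$sequence
  hit <- NULL
  for (k in 5:50) {
    cs <- 104L + 3L * (k - 1L)
    codon <- substr(refseq, cs, cs + 2L)
    for (sc in polyamp:::STOP_CODONS) {
      d <- which(strsplit(codon, "")[[1]] != strsplit(sc, "")[[1]])
      if (length(d) == 1L) { hit <- list(k = k, pos = cs + d - 1L, alt = substr(sc, d, d)); break }
    }
    if (!is.null(hit)) break
  }
  hs <- plant_variants(p, list(
    list(label = "null", genome = "B", freq = 1,
         events = data.frame(pos = hit$pos, ref = substr(refseq, hit$pos, hit$pos),
                             alt = hit$alt))))
  prot <- polyamp:::fast_translate(substr(hs$haps[[1]]$seq, 104, nchar(hs$haps[[1]]$seq)))
  expect_equal(regexpr("*", prot, fixed = TRUE)[1], hit$k)
})

test_that("a 72-nt GT..AG insertion lengthens the haplotype and is recorded", {
  p <- make_panel(33, length = 900, divergence = 0, cds_start = 104)
  seg <- paste0("GT", paste(rep("A", 68), collapse = ""), "AG")
  hs <- plant_variants(p, list(
    list(label = "iv", genome = "B", freq = 1,
         events = data.frame(pos = 300, ref = "", alt = seg),
         introns = data.frame(rp_start = 301, rp_end = 372, class = "canonical"))))
  expect_equal(nchar(hs$haps[[1]]$seq), 972L)
  tr <- truth_set(hs, panel_reference(p))
  expect_equal(tr$introns$class, "canonical")
  expect_equal(tr$introns$rp_end - tr$introns$rp_start + 1L, 72L)
  tv <- tr$variants
  expect_true(any(tv$type == "indel" & nchar(sub("^\\+", "", tv$alt)) == 72L))
})

test_that("truth fractions accumulate SNP and deletion spans by frequency", {
  p <- make_panel(34, length = 900, divergence = 0, cds_start = 104)
  region <- panel_reference(p)
  refseq <- region$sequence
  hs <- plant_variants(p, list(
    list(label = "a", genome = "B", freq = 0.7,
         events = data.frame(pos = 200, ref = substr(refseq, 200, 200),
                             alt = setdiff(c("A","C","G","T"), substr(refseq, 200, 200))[1])),
    list(label = "b", genome = "B", freq = 0.3,
         events = data.frame(pos = c(200, 400), ref = c(substr(refseq, 200, 200),
                                                        substr(refseq, 400, 402)),
                             alt = c(setdiff(c("A","C","G","T"), substr(refseq, 200, 200))[1], "")))))
  fr <- truth_fractions(hs, region)
  expect_equal(fr$nonref[fr$rp == 200], 1)      # both haplotypes
  expect_equal(fr$nonref[fr$rp == 401], 0.3)    # deletion span
  expect_equal(nrow(fr[fr$rp == 500]), 0L)
})

test_that("sample_reads: exact substrings at zero error, empty at depth 0", {
  p <- make_panel(35, length = 700, divergence = 0, cds_start = 104)
  hs <- plant_variants(p, list(list(label = "only", genome = "B", freq = 1,
                                    events = NULL)))
  res <- sample_reads(hs, 50, error_model(0, 0), seed = 3)
  tpl <- hs$haps[[1]]$seq
  for (i in seq_len(50)) {
    s <- res$reads$seq[i]
    if (!grepl(s, tpl, fixed = TRUE)) s <- polyamp:::revcomp(s)
    expect_true(grepl(s, tpl, fixed = TRUE))
  }
  empty <- sample_reads(hs, 0, error_model(0, 0), seed = 3)
  expect_length(empty$reads, 0L)
  expect_equal(nrow(empty$sources), 0L)
})

test_that("read sources follow the frequency vector within 3 binomial SE", {
  p <- make_panel(36, length = 700, divergence = 0.03, cds_start = 104)
  hs <- plant_variants(p, list(
    list(label = "h60", genome = "A", freq = 0.6, events = NULL),
    list(label = "h30", genome = "B", freq = 0.3, events = NULL),
    list(label = "h10", genome = "D", freq = 0.1, events = NULL)))
  depth <- 4000L
  res <- sample_reads(hs, depth, error_model(0, 0), seed = 8)
  emp <- table(res$sources$label) / depth
  for (f in c(h60 = 0.6, h30 = 0.3, h10 = 0.1)) {
    nm <- names(which(c(h60 = 0.6, h30 = 0.3, h10 = 0.1) == f))[1]
    se <- sqrt(f * (1 - f) / depth)
    expect_lt(abs(emp[[nm]] - f), 3 * se)
  }
})

test_that("identical seed and config give byte-identical FASTQ", {
  p <- make_panel(37, length = 700, divergence = 0.03, cds_start = 104)
  hs <- plant_variants(p)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fastq(sample_reads(hs, 200, error_model(), seed = 5)$reads, f1)
  write_fastq(sample_reads(hs, 200, error_model(), seed = 5)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile()
  write_fastq(sample_reads(hs, 200, error_model(), seed = 6)$reads, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("error model injects homopolymer-biased indels and clipped quals", {
  em <- error_model(substitution_rate = 0, indel_base_rate = 0.02, multiplier = 4)
  set.seed(41)
  homo <- paste0(strrep("C", 5), strrep("A", 30), strrep("G", 5))
  mixed <- paste(rep(c("A", "C", "G", "T"), 10), collapse = "")
  n_changed <- function(tpl) sum(replicate(200, nchar(polyamp:::inject_errors(tpl, em))) != nchar(tpl))
  expect_gt(n_changed(homo), n_changed(mixed))
  q <- polyamp:::sim_qualities(500, error_model())
  expect_true(all(phred_scores(q) >= 2 & phred_scores(q) <= 40))
  expect_error(error_model(substitution_rate = 2), "substitution_rate")
})
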
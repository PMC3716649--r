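# a coding region with a clean frame for intron planting
mk_coding_region <- function(n_codons = 120, seed = 51) {
  set.seed(seed)
  reference_region("r", paste0("CCCCCCCCCC", "ATG",
                               paste(sample(polyamp:::SAFE_CODONS, n_codons,
                                            replace = TRUE), collapse = "")),
                   cds_start_rp = 11L)
}

INTRON72 <- paste0("GTA", "TAA", paste(rep(c("GCT", "GAA", "CTG"), 7), collapse = ""), "AAG")

test_that("frame disruption arithmetic: net -43 disrupts, -42 does not", {
  region <- mk_coding_region()
  refseq <- region$sequence
  # 42-nt deletion (codon boundary) plus a separate single-base deletion
  s1 <- 32L; s2 <- 120L
  cons <- paste0(substr(refseq, 11, s1 - 1), substr(refseq, s1 + 42, s2 - 1),
                 substr(refseq, s2 + 1, nchar(refseq)))
  ev <- sprintf("%ddel%s;%ddel%s", s1, substr(refseq, s1, s1 + 41),
                s2, substr(refseq, s2, s2))
  dis <- detect_frame_disruption(list(consensus = cons, event_string = ev),
                                 region, 11L)
  expect_equal(dis$net_nt, -43L)
  expect_true(dis$frame_residue != 0L)
  expect_true(dis$disrupted)
  # -42 nt alone: a multiple of 3, no disruption (no stop introduced)
  cons2 <- paste0(substr(refseq, 11, s1 - 1), substr(refseq, s1 + 42, nchar(refseq)))
  ev2 <- sprintf("%ddel%s", s1, substr(refseq, s1, s1 + 41))
  dis2 <- detect_frame_disruption(list(consensus = cons2, event_string = ev2),
                                  region, 11L)
  expect_equal(dis2$net_nt, -42L)
  expect_false(dis2$disrupted)
})

test_that("net change 0 with a planted stop is a disruption", {
  region <- mk_coding_region()
  refseq <- region$sequence
  # put TAA at codon 20 (rp 68..70)
  cons <- substr(refseq, 11, nchar(refseq))
  old <- substring(refseq, 68:70, 68:70)
  substr(cons, 58, 60) <- "TAA"
  diff <- which(old != c("T", "A", "A"))
  et <- polyamp:::edit_table(67L + diff, old[diff], c("T", "A", "A")[diff])
  dis <- detect_frame_disruption(list(consensus = cons,
                                      event_string = polyamp:::edits_to_string(et)),
                                 region, 11L)
  expect_equal(dis$net_nt, 0L)
  expect_true(dis$premature_stop)
  expect_true(dis$disrupted)
})

plant_intron <- function(region, anchor, seg) {
  refseq <- region$sequence
  cons <- paste0(substr(refseq, 11, anchor), seg,
                 substr(refseq, anchor + 1, nchar(refseq)))
  list(consensus = cons, event_string = sprintf("%dins%s", anchor, seg))
}

test_that("a planted 72-nt GT..AG insertion is the top-ranked canonical call", {
  region <- mk_coding_region()
  anchor <- 11L + 59L            # third base of codon 20
  var <- plant_intron(region, anchor, INTRON72)
  calls <- scan_introns(var, region, 11L)
  expect_gt(nrow(calls), 0L)
  top <- calls[calls$rank == 1L, ]
  expect_equal(top$class, "canonical")
  expect_equal(top$length, 72L)
  expect_equal(top$donor, "GT")
  expect_equal(top$acceptor, "AG")
  expect_true(top$frame_restored)
  expect_equal(top$residues_deleted, 0L)
  # splicing the top call restores the reference protein
  spl <- splice_and_translate(var, as.data.frame(top), region, 11L)
  expect_equal(spl$protein, polyamp:::fast_translate(substr(region$sequence, 11,
                                                            nchar(region$sequence))))
})

test_that("all returned calls restore frame (net == 0 mod 3 after removal)", {
  region <- mk_coding_region()
  var <- plant_intron(region, 11L + 59L, INTRON72)
  calls <- scan_introns(var, region, 11L, max_len = 100L)
  net <- 72L
  expect_true(all((net - calls$length) %% 3L == 0L))
  # among equal-scoring candidates of equal length, canonical ranks first
  dt <- as.data.frame(calls)
  dt$grp <- paste(dt$length, signif(dt$spliced_identity, 12))
  for (g in unique(dt$grp)) {
    sub <- dt[dt$grp == g, ]
    if (length(unique(sub$class)) == 2L)
      expect_lt(min(sub$rank[sub$class == "canonical"]),
                min(sub$rank[sub$class == "non_canonical"]))
  }
})

test_that("a retained 5-nt segment is called with 2 residues deleted", {
  region <- mk_coding_region(seed = 53)
  refseq <- region$sequence
  # choose codon-boundary site at rp 50 (codon 14 starts at 11+39=50)
  p <- 50L
  r <- substring(refseq, p:(p + 5L), p:(p + 5L))
  # variant: r1 r2 r4 r5 r6 with boundaries forced to AC..AT
  seg <- paste0("AC", r[4L], "AT")
  cons <- paste0(substr(refseq, 11, p - 1L), seg, substr(refseq, p + 6L, nchar(refseq)))
  ev <- "50construct"  # event string only feeds net/projection; build properly:
  et <- polyamp:::edit_table(
    pos = c(p, p + 1L, p + 2L, p + 4L, p + 5L)[c(r[1] != "A", r[2] != "C", TRUE,
                                                 r[5] != "A", r[6] != "T")],
    ref = c(r[1], r[2], r[3], r[5], r[6])[c(r[1] != "A", r[2] != "C", TRUE,
                                            r[5] != "A", r[6] != "T")],
    alt = c("A", "C", "", "A", "T")[c(r[1] != "A", r[2] != "C", TRUE,
                                      r[5] != "A", r[6] != "T")])
  var <- list(consensus = cons, event_string = polyamp:::edits_to_string(et))
  dis <- detect_frame_disruption(var, region, 11L)
  expect_equal(dis$net_nt, -1L)
  calls <- scan_introns(var, region, 11L, min_identity = 0.9)
  expect_gt(nrow(calls), 0L)
  top <- calls[calls$rank == 1L, ]
  expect_equal(top$length, 5L)
  expect_equal(top$residues_deleted, 2L)
  expect_true(top$frame_restored)
  # the spliced product has the reference protein minus two residues
  spl <- splice_and_translate(var, as.data.frame(top), region, 11L)
  ref_prot <- polyamp:::fast_translate(substr(refseq, 11, nchar(refseq)))
  expect_equal(nchar(spl$protein), nchar(ref_prot) - 2L)
})

test_that("scan agrees with exhaustive enumeration (completeness)", {
  region <- mk_coding_region(60, seed = 55)
  var <- plant_intron(region, 11L + 29L, INTRON72)
  calls <- scan_introns(var, region, 11L, max_len = 90L)
  oracle <- oracle_scan_intervals(var$consensus, net = 72L, skip = 0L, max_len = 90L)
  got <- sort(paste(calls$start, calls$end))
  want <- sort(paste(oracle$start, oracle$end))
  expect_equal(got, want)
})

test_that("no resolvable interval yields an empty list", {
  region <- mk_coding_region(40, seed = 56)
  refseq <- region$sequence
  # single-base deletion with max_len too small to restore frame cleanly:
  # use max_len 4 and a consensus whose only L=2 candidates are below min len
  p <- 60L
  cons <- paste0(substr(refseq, 11, p - 1L), substr(refseq, p + 1L, nchar(refseq)))
  var <- list(consensus = cons,
              event_string = sprintf("%ddel%s", p, substr(refseq, p, p)))
  calls <- scan_introns(var, region, 11L, max_len = 4L)
  expect_equal(nrow(calls), 0L)
})

test_that("splice_and_translate removes multiple introns and checks overlap", {
  region <- mk_coding_region(120, seed = 57)
  refseq <- region$sequence
  ref_prot <- polyamp:::fast_translate(substr(refseq, 11, nchar(refseq)))
  a1 <- 11L + 29L; a2 <- 11L + 200L
  cons <- paste0(substr(refseq, 11, a1), INTRON72,
                 substr(refseq, a1 + 1L, a2), "ACGAT",
                 substr(refseq, a2 + 1L, nchar(refseq)))
  var <- list(consensus = cons,
              event_string = sprintf("%dins%s;%dins%s", a1, INTRON72, a2, "ACGAT"))
  i1 <- a1 - 11L + 2L
  i2 <- a2 - 11L + 72L + 2L
  calls <- data.frame(start = c(i1, i2), end = c(i1 + 71L, i2 + 4L))
  # note: the 5-nt insertion breaks frame; removing both restores it
  spl <- splice_and_translate(var, calls, region, 11L)
  expect_equal(spl$protein, ref_prot)
  # overlapping calls error
  bad <- data.frame(start = c(10L, 50L), end = c(60L, 90L))
  expect_error(splice_and_translate(var, bad, region, 11L), "overlap")
  # no calls -> direct translation
  direct <- splice_and_translate(var, NULL, region, 11L)
  expect_equal(direct$spliced, var$consensus)
})
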
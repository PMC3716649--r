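# End-to-end orchestration: trim -> align -> pileup -> call -> haplotype ->
# consequence -> intron scan, plus the demonstration pool that exercises
# every stage with known truth.

#' Demonstration amplicon layout for a 1902-nt reference
#'
#' Three amplicons mirroring a typical tiling of a DELLA-family gene: one
#' over the two N-terminal GA-signal motifs, one in the mid GRAS domain
#' (where putative introns are sought) and one at the C terminus.  Primer
#' sequences are taken from the reference itself.
#'
#' @param region a [reference_region()] of length >= 1902.
#' @export
demo_amplicons <- function(region) {
  n <- nchar(region$sequence)
  stopifnot(n >= 1800L)
  iv <- data.frame(pair_name = c("F2/R2", "F4/R4", "F6/R6"),
                   rp_start = c(260L, 764L, 1571L) + region$rp_offset,
                   rp_end = c(532L, 1138L, n) + region$rp_offset)
  s <- rp_to_internal(region, iv$rp_start)
  e <- rp_to_internal(region, iv$rp_end)
  fwd <- substring(region$sequence, s, s + 19L)
  rev <- revcomp(substring(region$sequence, e - 19L, e))
  amplicon_set(iv$pair_name, fwd, rev, iv$rp_start, iv$rp_end)
}

# scan for a codon (kmin..kmax, ref coords) free of divergence events,
# >= min_gap from already-used positions; returns ref pos of codon base 1
.find_free_codon <- function(refch, cds0, span, kmin, kmax, used, min_gap = 8L) {
  for (k in kmin:kmax) {
    p <- cds0 + 3L * (k - 1L)
    if (length(used) && min(abs(used - p)) < min_gap + 2L) next
    if (nrow(span) && any(pmax(p - 5L, span$start) <= pmin(p + 7L, span$end))) next
    return(p)
  }
  stop("no free codon found in ", kmin, "..", kmax)
}

#' Demonstration haplotype pool
#'
#' Builds the planted-variant specification the package's end-to-end tests
#' run on: a clean B-genome "type" haplotype; an A-genome haplotype with
#' five SNPs (one creating a stop codon inside the DELLA interval), a 3-nt
#' in-frame codon deletion, and a single-base deletion leaving a 5-nt
#' AC..AT retained segment (a non-canonical intron mimic); and a D-genome
#' haplotype carrying a 72-nt GT..AG intron-like insertion containing an
#' in-frame stop.  Site selection is deterministic given the panel.
#'
#' @param panel a `homeolog_panel`.
#' @param freqs pool frequencies of the three haplotypes (sum 1).
#' @return list of specs for [plant_variants()].
#' @export
demo_pool_specs <- function(panel, freqs = c(0.6, 0.3, 0.1)) {
  stopifnot(length(freqs) == 3L, abs(sum(freqs) - 1) < 1e-9)
  region <- panel_reference(panel)
  ref <- region$sequence
  refch <- strsplit(ref, "", fixed = TRUE)[[1L]]
  cds0 <- panel$genomes$B$cds_start
  genA <- panel$genomes$A
  genD <- panel$genomes$D
  spanA <- edit_span(genA$edits_vs_ref)
  spanD <- edit_span(genD$edits_vs_ref)
  used <- integer()
  evA_pos <- integer(); evA_ref <- character(); evA_alt <- character()
  bases <- c("A", "C", "G", "T")

  # 1. nonsense SNP inside the DELLA interval (codons 40-75), within the
  #    first coding amplicon
  non_p <- NA_integer_
  for (k in 62:75) {   # inside the DELLA interval, clear of the primer zone
    p <- cds0 + 3L * (k - 1L)
    if (nrow(spanA) && any(pmax(p - 5L, spanA$start) <= pmin(p + 7L, spanA$end))) next
    codon <- substr(ref, p, p + 2L)
    for (sc in STOP_CODONS) {
      d <- which(strsplit(codon, "")[[1L]] != strsplit(sc, "")[[1L]])
      if (length(d) == 1L) {
        non_p <- p + d - 1L
        evA_pos <- c(evA_pos, non_p)
        evA_ref <- c(evA_ref, refch[non_p])
        evA_alt <- c(evA_alt, substr(sc, d, d))
        break
      }
    }
    if (!is.na(non_p)) break
  }
  if (is.na(non_p)) stop("no nonsense site available in the DELLA interval")
  used <- c(used, non_p)

  # 2. four further SNPs in the same amplicon (non-stop alts)
  kpref <- c(78L, 90L, 102L, 114L)
  for (k0 in kpref) {
    p <- .find_free_codon(refch, cds0, spanA, k0, k0 + 11L, used)
    codon <- substr(ref, p, p + 2L)
    alt <- NA_character_
    for (b in bases[bases != refch[p]]) {
      cand <- codon
      substr(cand, 1L, 1L) <- b
      if (!cand %in% STOP_CODONS) { alt <- b; break }
    }
    evA_pos <- c(evA_pos, p); evA_ref <- c(evA_ref, refch[p]); evA_alt <- c(evA_alt, alt)
    used <- c(used, p)
  }

  # 3. in-frame deletion of one full codon (single-residue deletion), on
  # the D haplotype so the protein diff is not truncated upstream by the
  # A haplotype's nonsense codon; kept clear of the reverse-primer zone
  # (primer synthesis would overwrite bases its span touches)
  pdel <- .find_free_codon(refch, cds0, spanD, 126L, 133L, used)
  evD_pos <- pdel; evD_ref <- substr(ref, pdel, pdel + 2L); evD_alt <- ""
  used <- c(used, pdel)

  # 4. retained 5-nt AC..AT segment in the mid-GRAS amplicon: delete one of
  #    six reference bases (two codons) and substitute boundary bases so the
  #    remaining 5-mer reads AC..AT; removal of the 5-mer deletes 2 residues
  k_lo <- (812L - cds0) %/% 3L + 2L
  k_hi <- (1085L - cds0) %/% 3L
  best <- NULL
  for (k in k_lo:k_hi) {
    p <- cds0 + 3L * (k - 1L)
    r <- refch[p:(p + 5L)]
    if (r[2L] == r[3L] || r[3L] == r[4L]) next  # keep the deletion unambiguous
    if (nrow(spanA) && any(pmax(p - 5L, spanA$start) <= pmin(p + 11L, spanA$end))) next
    # reject sites where a shifted removal is junction-equivalent (local
    # repeats would make the splice interval ambiguous)
    v5 <- c("A", "C", r[4L], "A", "T")
    ctx <- c(refch[(p - 5L):(p - 1L)], v5, refch[(p + 6L):(p + 10L)])
    ok <- TRUE
    for (d in 1:5) {
      if (identical(ctx[6L:(5L + d)], ctx[11L:(10L + d)])) ok <- FALSE
      if (identical(ctx[(6L - d):5L], ctx[(11L - d):10L])) ok <- FALSE
      if (identical(refch[p:(p + d - 1L)], refch[(p + 6L):(p + 5L + d)])) ok <- FALSE
      if (identical(refch[(p - d):(p - 1L)], refch[(p + 6L - d):(p + 5L)])) ok <- FALSE
    }
    if (!ok) next
    need <- sum(r[1L] != "A", r[2L] != "C", r[5L] != "A", r[6L] != "T")
    if (is.null(best) || need < best$need) best <- list(p = p, r = r, need = need)
    if (best$need == 0L) break
  }
  if (is.null(best)) stop("no retained-segment site available")
  p <- best$p; r <- best$r
  tgt <- c("A", "C", NA, NA, "A", "T")   # positions p..p+5; p+2 deleted, p+3 free
  for (off in c(0L, 1L, 4L, 5L)) {
    if (r[off + 1L] != tgt[off + 1L]) {
      evA_pos <- c(evA_pos, p + off); evA_ref <- c(evA_ref, r[off + 1L])
      evA_alt <- c(evA_alt, tgt[off + 1L])
    }
  }
  evA_pos <- c(evA_pos, p + 2L); evA_ref <- c(evA_ref, r[3L]); evA_alt <- c(evA_alt, "")
  retained_iv <- c(p, p + 5L)

  # 5. 72-nt GT..AG insertion with an in-frame stop, on the D haplotype,
  #    anchored at a codon boundary >= 40 nt from the retained segment
  seg <- paste0("GTA", "TAA",
                paste(rep(c("GCT", "GAA", "CTG"), 7L), collapse = ""), "AAG")
  stopifnot(nchar(seg) == 72L)
  ins_a <- NA_integer_
  for (k in ((830L - cds0) %/% 3L + 1L):((1040L - cds0) %/% 3L)) {
    a <- cds0 + 3L * k - 1L           # third base of codon k
    if (abs(a - p) < 40L) next
    if (nrow(spanD) && any(pmax(a - 5L, spanD$start) <= pmin(a + 6L, spanD$end))) next
    ins_a <- a
    break
  }
  if (is.na(ins_a)) stop("no insertion anchor available")

  # express events in backbone coordinates
  to_backbone <- function(gen, pos) map_ref_pos(gen$edits_vs_ref, pos)
  evA <- data.frame(pos = to_backbone(genA, evA_pos), ref = evA_ref, alt = evA_alt,
                    stringsAsFactors = FALSE)
  evD <- data.frame(pos = to_backbone(genD, c(evD_pos, ins_a)),
                    ref = c(evD_ref, ""), alt = c(evD_alt, seg),
                    stringsAsFactors = FALSE)
  out <- list(
    list(label = "type_B", genome = "B", freq = freqs[1L], events = NULL),
    list(label = "null_A", genome = "A", freq = freqs[2L], events = evA,
         introns = data.frame(rp_start = internal_to_rp(region, retained_iv[1L]),
                              rp_end = internal_to_rp(region, retained_iv[2L]),
                              length = 5L, class = "non_canonical")),
    list(label = "intron_D", genome = "D", freq = freqs[3L], events = evD,
         introns = data.frame(rp_start = internal_to_rp(region, ins_a + 1L),
                              rp_end = internal_to_rp(region, ins_a + 72L),
                              length = 72L, class = "canonical")))
  attr(out, "sites") <- list(
    nonsense_rp = internal_to_rp(region, non_p),
    snp_rps = internal_to_rp(region, utils::head(used[-1L], 4L)),
    del_rp = internal_to_rp(region, pdel),
    retained_rp = internal_to_rp(region, p),
    ins_anchor_rp = internal_to_rp(region, ins_a))
  out
}

#' Simulate a multi-library amplicon pool with truth
#'
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param n_libraries number of libraries (accessions) to emit.
#' @param depth reads per amplicon per library.
#' @param divergence backbone divergence.
#' @param length backbone length.
#' @param em an [error_model()].
#' @param out_dir optional directory: writes FASTQ per library, reference
#'   FASTA, amplicon TSV and the truth files.
#' @return list: panel, region, amplicons, hapset, truth,
#'   libraries (named list of [fastq_set]), sources.
#' @export
simulate_pool <- function(seed = 1L, n_libraries = 3L, depth = 2000L,
                          divergence = 0.05, length = 1902L,
                          em = error_model(), out_dir = NULL) {
  # site selection can fail for an unlucky arrangement of divergence events;
  # retry with a reseeded panel (bounded, deterministic)
  panel <- NULL; hapset <- NULL; sites <- NULL
  for (try in 0:9) {
    panel <- make_panel((seed + 101L * try) %% 2147483647L,
                        length = length, divergence = divergence)
    hapset <- tryCatch({
      specs <- demo_pool_specs(panel)
      sites <- attr(specs, "sites")
      plant_variants(panel, specs)
    }, error = function(e) NULL)
    if (!is.null(hapset)) break
  }
  if (is.null(hapset)) stop("could not construct a demonstration pool")
  region <- panel_reference(panel)
  amplicons <- demo_amplicons(region)
  truth <- truth_set(hapset, region)
  libraries <- list(); sources <- list()
  for (l in seq_len(n_libraries)) {
    nm <- sprintf("lib%d", l)
    res <- amplicon_pool(hapset, region, amplicons, depth, em,
                         seed = (seed * 1000L + l) %% 2147483647L, lib = nm)
    libraries[[nm]] <- res$reads
    sources[[nm]] <- res$sources
  }
  out <- list(panel = panel, region = region, amplicons = amplicons,
              hapset = hapset, truth = truth, sites = sites,
              libraries = libraries,
              sources = data.table::rbindlist(sources))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(stats::setNames(region$sequence, region$name),
                file.path(out_dir, "reference.fasta"))
    utils::write.table(as.data.frame(amplicons),
                       file.path(out_dir, "amplicons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(libraries))
      write_fastq(libraries[[nm]], file.path(out_dir, paste0(nm, ".fastq")))
    write_truth(truth, out_dir)
    writeLines(c(sprintf("seed=%d", seed), sprintf("n_libraries=%d", n_libraries),
                 sprintf("depth=%d", depth), sprintf("divergence=%g", divergence),
                 sprintf("length=%d", length)),
               file.path(out_dir, "config.txt"))
  }
  out
}

#' Run the full analysis pipeline on read libraries
#'
#' trim -> align -> pileup -> per-library calls -> combined report ->
#' per-amplicon haplotypes (per library) -> protein consequences of
#' accepted coding SNPs -> intron scan of frame-disrupted variants.
#'
#' @param libraries named list of [fastq_set] (one per library/accession).
#' @param region the [reference_region()].
#' @param amplicons an [amplicon_set()].
#' @param panel optional `homeolog_panel` used for allele assignment of
#'   amplicon variants.
#' @param trim_cfg,align_cfg,call_cfg,hap_cfg stage configurations.
#' @param motifs a [motif_set()].
#' @param max_intron_len passed to [scan_introns()].
#' @param out_dir optional output directory for the report files.
#' @return list: trim_summary, combined (table + summary), variants
#'   (per amplicon: per-library tables + frequency matrix + assignments),
#'   consequences (records + tally), introns (per disrupted variant),
#'   manifest.
#' @export
run_pipeline <- function(libraries, region, amplicons, panel = NULL,
                         trim_cfg = trim_config(), align_cfg = align_config(),
                         call_cfg = call_config(), hap_cfg = hap_config(),
                         motifs = motif_set(), max_intron_len = 200L,
                         out_dir = NULL) {
  stopifnot(length(libraries) >= 1L, !is.null(names(libraries)))
  trims <- list(); alns <- list(); lib_calls <- list()
  for (nm in names(libraries)) {
    tr <- trim_library(libraries[[nm]], trim_cfg)
    trims[[nm]] <- tr$summary
    aln <- align_reads(tr$reads, region, align_cfg, amplicons = amplicons)
    alns[[nm]] <- aln
    pile <- build_pileup(aln, region, amplicons)
    lib_calls[[nm]] <- call_pileup(pile, region, call_cfg, library = nm)
  }
  combined <- combine_reports(lib_calls, call_cfg)
  accepted <- combined$table[combined$table$accepted, ]

  variants <- list()
  for (k in seq_len(nrow(amplicons))) {
    pn <- amplicons$pair_name[k]
    per_lib <- list()
    for (nm in names(libraries)) {
      per_lib[[nm]] <- suppressWarnings(
        group_reads(alns[[nm]], region, amplicons$rp_start[k],
                    amplicons$rp_end[k], accepted, hap_cfg, pair_name = pn))
    }
    fmat <- frequency_table(per_lib)
    assignments <- NULL
    if (!is.null(panel)) {
      s <- rp_to_internal(region, amplicons$rp_start[k])
      e <- rp_to_internal(region, amplicons$rp_end[k])
      pan <- do.call(rbind, lapply(c("A", "B", "D"), function(g) {
        gen <- panel$genomes[[g]]
        iv <- map_ref_interval(gen$edits_vs_ref, s, e)
        data.frame(allele_name = paste0("backbone_", g), genome_label = g,
                   sequence = substr(gen$seq, iv[1L], iv[2L]),
                   stringsAsFactors = FALSE)
      }))
      seen <- unique(data.table::rbindlist(per_lib)[, .(event_string, consensus)])
      assignments <- do.call(rbind, lapply(seq_len(nrow(seen)), function(i) {
        a <- assign_allele(seen$consensus[i], pan)
        data.frame(event_string = seen$event_string[i],
                   allele_name = a$allele_name, genome_label = a$genome_label,
                   identity_pct = a$identity_pct, ambiguous = a$ambiguous,
                   stringsAsFactors = FALSE)
      }))
    }
    variants[[pn]] <- list(per_library = per_lib, frequencies = fmat,
                           assignments = assignments)
  }

  # consequences of accepted coding SNPs
  cons <- NULL
  if (!is.na(region$cds_start_rp) && nrow(accepted)) {
    snps <- as.data.frame(accepted)
    snps <- snps[snps$type == "snp", ]
    if (nrow(snps)) {
      cons_rows <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i)
        annotate_snp(snps$rp[i], snps$ref[i], snps$alt[i], region, motifs)))
      cons <- list(records = cons_rows, tally = tally_consequences(cons_rows))
    }
  }

  # intron scan of frame-disrupted amplicon variants (deduplicated)
  introns <- list(); scanned <- character()
  for (k in seq_len(nrow(amplicons))) {
    pn <- amplicons$pair_name[k]
    for (nm in names(variants[[pn]]$per_library)) {
      vt <- variants[[pn]]$per_library[[nm]]
      for (i in seq_len(nrow(vt))) {
        key <- vt$consensus[i]
        if (key %in% scanned) next
        scanned <- c(scanned, key)
        dis <- detect_frame_disruption(vt[i, ], region, amplicons$rp_start[k])
        if (!dis$disrupted) next
        calls <- scan_introns(vt[i, ], region, amplicons$rp_start[k],
                              max_len = max_intron_len, min_identity = 0.7)
        introns[[length(introns) + 1L]] <- list(
          pair_name = pn, library = nm, variant_id = vt$variant_id[i],
          event_string = vt$event_string[i], disruption = dis, calls = calls)
      }
    }
  }

  manifest <- list(libraries = names(libraries),
                   trim = unclass(trim_cfg), align = unclass(align_cfg),
                   call = unclass(call_cfg), hap = unclass(hap_cfg),
                   max_intron_len = max_intron_len)
  out <- list(trim_summary = do.call(rbind, trims), combined = combined,
              variants = variants, consequences = cons, introns = introns,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_variant_report(combined$table, file.path(out_dir, "variant_report.tsv"))
    jsonlite::write_json(combined$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    for (pn in names(variants)) {
      fn <- gsub("/", "", pn)
      hap_tab <- data.table::rbindlist(
        lapply(names(variants[[pn]]$per_library), function(nm) {
          d <- data.table::copy(variants[[pn]]$per_library[[nm]])
          d[, library := nm]
          d[, consensus := NULL]
          d
        }))
      utils::write.table(hap_tab, file.path(out_dir, paste0("haplotypes_", fn, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
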
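# Synthetic hexaploid amplicon-pool generator with a recorded truth set.
#
# Three homeolog backbones (A, B, D) are derived from a common ancestor by
# independent substitutions and short (1-3 nt) indels; indels inside the
# CDS are constrained to 3 nt so every backbone stays in frame and
# stop-free, as real homeologs of a functional gene family are.  The B
# backbone doubles as the pipeline reference (the study design this
# emulates aligned all libraries against a single B-genome allele), and
# every haplotype carries an exact edit list against that reference, so
# per-position truth fractions and the expected variant report are
# computed analytically, never via an aligner.

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

SAFE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                       c("TAA", "TAG", "TGA"))

# first internal stop in the CDS translation, or NA
cds_has_stop <- function(seq, cds_start) {
  body <- substr(seq, cds_start, nchar(seq))
  st <- codon_starts(nchar(body))
  if (length(st) < 2L) return(FALSE)
  codons <- substring(body, st, st + 2L)
  any(codons[-length(codons)] %in% STOP_CODONS)
}

# draw one genome's divergence edits from its reserved positions
genome_edits <- function(ancestor, cds_start, sub_pos, indel_pos, utr_ok) {
  n <- nchar(ancestor)
  pos <- integer(); ref <- character(); alt <- character()
  anc_ch <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
  cur <- anc_ch  # track per-codon substitutions for stop avoidance
  for (p in sub_pos) {
    choices <- sample(setdiff(c("A", "C", "G", "T"), anc_ch[p]))
    picked <- NA_character_
    for (b in choices) {
      if (p >= cds_start + 3L) {
        ci <- (p - cds_start) %/% 3L
        cs <- cds_start + 3L * ci
        codon <- cur[cs:(cs + 2L)]
        codon[p - cs + 1L] <- b
        if (paste(codon, collapse = "") %in% STOP_CODONS) next
      }
      picked <- b
      break
    }
    if (is.na(picked)) next
    cur[p] <- picked
    pos <- c(pos, p); ref <- c(ref, anc_ch[p]); alt <- c(alt, picked)
  }
  for (p in indel_pos) {
    in_utr <- p < cds_start - 4L
    len <- if (in_utr && utr_ok) sample(1:3, 1L) else 3L
    if (stats::runif(1) < 0.5 && p + len - 1L <= n) {   # deletion
      pos <- c(pos, p); ref <- c(ref, substr(ancestor, p, p + len - 1L)); alt <- c(alt, "")
    } else {                                            # insertion after p
      ins <- if (in_utr && utr_ok) rand_dna(len) else sample(SAFE_CODONS, 1L)
      pos <- c(pos, p); ref <- c(ref, ""); alt <- c(alt, ins)
    }
  }
  normalize_edits(edit_table(pos, ref, alt), ancestor)
}

#' Generate a three-homeolog panel
#'
#' @param seed integer seed; identical (seed, parameters) give identical
#'   panels.
#' @param length backbone length in nt (>= 300).
#' @param divergence target pairwise divergence between backbones (0 gives
#'   three identical backbones; must be < 0.2).
#' @param cds_start 1-based position of the ATG in the ancestor.
#' @return an object of class `homeolog_panel`: `ancestor`, `cds_start`,
#'   and `genomes` (named list A/B/D, each with `seq`, `cds_start`,
#'   `edits_anc` (vs ancestor) and `edits_vs_ref` (vs the B backbone, in
#'   reference coordinates)).
#' @export
make_panel <- function(seed, length = 1902L, divergence = 0.05,
                       cds_start = 104L) {
  stopifnot(length >= 300L, divergence >= 0, divergence < 0.2,
            cds_start >= 1L, cds_start + 2L <= length)
  set.seed(seed)
  utr <- rand_dna(cds_start - 1L)
  ncod <- (length - cds_start + 1L - 3L) %/% 3L
  rest <- (length - cds_start + 1L - 3L) %% 3L
  ancestor <- paste0(utr, "ATG",
                     paste(sample(SAFE_CODONS, ncod, replace = TRUE), collapse = ""),
                     rand_dna(rest))
  n_indel <- if (divergence > 0) 2L else 0L
  # discount the expected gap columns the indels add to pairwise alignments
  n_sub <- max(0L, round(divergence / 2 * length) - 2L * n_indel)
  utr_ok <- cds_start >= 20L
  # reserve well-spaced positions, disjoint across genomes, so that edits
  # never overlap after left-alignment and backbone diffs compose cleanly
  pool <- sample(setdiff(11:(length - 10L), cds_start:(cds_start + 2L)))
  m <- 3L * (n_sub + n_indel) + 12L
  gap <- max(4L, min(8L, (length - 20L) %/% max(m, 1L)))
  accepted <- integer()
  for (p in pool) {
    if (!length(accepted) || min(abs(accepted - p)) >= gap)
      accepted <- c(accepted, p)
    if (length(accepted) >= m) break
  }
  if (length(accepted) < 3L * (n_sub + n_indel))
    stop("sequence too short for the requested divergence")
  genomes <- list()
  remaining <- accepted
  need <- n_sub + n_indel
  for (g in c("A", "B", "D")) {
    for (attempt in 1:25) {
      sel <- if (need > 0L) sample(remaining, need) else integer()
      sub_pos <- sort(utils::head(sel, n_sub))
      indel_pos <- sort(utils::tail(sel, n_indel))
      et <- genome_edits(ancestor, cds_start, sub_pos, indel_pos, utr_ok)
      seq_g <- apply_edits(ancestor, et)
      cs_g <- map_ref_pos(et, cds_start)
      if (!cds_has_stop(seq_g, cs_g) &&
          substr(seq_g, cs_g, cs_g + 2L) == "ATG") {
        genomes[[g]] <- list(seq = seq_g, cds_start = cs_g, edits_anc = et)
        remaining <- setdiff(remaining, sel)
        break
      }
      if (attempt == 25L) stop("could not generate a stop-free backbone for genome ", g)
    }
  }
  refseq <- genomes$B$seq
  for (g in c("A", "B", "D")) {
    dvr <- if (g == "B") empty_edits() else
      normalize_edits(diff_against(genomes[[g]]$edits_anc, genomes$B$edits_anc), refseq)
    genomes[[g]]$edits_vs_ref <- dvr
  }
  structure(list(ancestor = ancestor, cds_start = as.integer(cds_start),
                 genomes = genomes),
            class = "homeolog_panel")
}

#' @export
print.homeolog_panel <- function(x, ...) {
  cat(sprintf("<homeolog_panel> %d nt backbones, CDS start %d; divergence events: A=%d B=%d D=%d\n",
              nchar(x$genomes$B$seq), x$cds_start,
              nrow(x$genomes$A$edits_vs_ref), nrow(x$genomes$B$edits_vs_ref),
              nrow(x$genomes$D$edits_vs_ref)))
  invisible(x)
}

#' The pipeline reference derived from a panel (the B backbone)
#' @param panel a `homeolog_panel`.
#' @param name reference name.
#' @param rp_offset RP offset for reporting.
#' @export
panel_reference <- function(panel, name = "synthetic_ref", rp_offset = 0L) {
  reference_region(name, panel$genomes$B$seq, rp_offset,
                   cds_start_rp = panel$genomes$B$cds_start + rp_offset)
}

#' Mean pairwise identity of the panel backbones
#' @param panel a `homeolog_panel`.
#' @export
panel_identity <- function(panel) {
  pairs <- utils::combn(c("A", "B", "D"), 2L)
  ids <- apply(pairs, 2L, function(p)
    global_identity(panel$genomes[[p[1L]]]$seq, panel$genomes[[p[2L]]]$seq)["identity"])
  mean(ids)
}

#' Plant haplotype variants on panel backbones
#'
#' @param panel a `homeolog_panel`.
#' @param specs list of haplotype specifications, each a list with `label`,
#'   `genome` ("A"/"B"/"D"), `freq` (fraction of the whole pool), `events`
#'   (data.frame pos/ref/alt in that genome's backbone coordinates; NULL or
#'   empty for an unmodified backbone) and optional `introns` (data.frame
#'   rp_start/rp_end/class annotated into the truth set).  An empty `specs`
#'   yields the three backbones at 1/3 each.
#' @return an object of class `haplotype_set`: list of haplotypes, each
#'   with label, genome, freq, seq, cds_start and `edits_vs_ref` (combined
#'   divergence + planted events, reference coordinates, left-aligned).
#' @export
plant_variants <- function(panel, specs = list()) {
  if (length(specs) == 0L)
    specs <- lapply(c("A", "B", "D"), function(g)
      list(label = paste0("backbone_", g), genome = g, freq = 1 / 3, events = NULL))
  total <- sum(vapply(specs, function(s) s$freq, 1))
  if (abs(total - 1) > 1e-9)
    stop(sprintf("haplotype frequencies sum to %.12f, not 1", total))
  refseq <- panel$genomes$B$seq
  haps <- lapply(specs, function(s) {
    gen <- panel$genomes[[s$genome]]
    if (is.null(gen)) stop("unknown genome label: ", s$genome)
    ev <- s$events
    et_b <- if (is.null(ev) || NROW(ev) == 0L) empty_edits()
            else edit_table(ev$pos, ev$ref, ev$alt)
    validate_edits(et_b, gen$seq)
    seq_h <- apply_edits(gen$seq, et_b)
    # planted events, re-expressed in reference coordinates
    ib <- invert_edits(gen$edits_vs_ref)    # backbone -> reference
    if (nrow(et_b)) {
      sp <- edit_span(et_b)
      isp <- edit_span(ib)
      if (nrow(ib))
        for (i in seq_len(nrow(et_b)))
          if (any(pmax(sp$start[i] - 1L, isp$start) <= pmin(sp$end[i] + 1L, isp$end)))
            stop("planted event at backbone position ", et_b$pos[i],
                 " overlaps a divergence event; choose another site")
      mapped <- edit_table(map_ref_pos(ib, et_b$pos), et_b$ref, et_b$alt)
    } else mapped <- empty_edits()
    combined <- rbind(gen$edits_vs_ref, mapped)
    combined <- normalize_edits(edit_table(combined$pos, combined$ref, combined$alt),
                                refseq)
    list(label = s$label, genome = s$genome, freq = s$freq, seq = seq_h,
         cds_start = map_ref_pos(et_b, gen$cds_start),
         edits_vs_ref = combined,
         introns = s$introns)
  })
  names(haps) <- vapply(haps, function(h) h$label, "")
  structure(list(haps = haps, reference = refseq), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes:\n", length(x$haps)))
  for (h in x$haps)
    cat(sprintf("  %-18s genome %s  freq %5.1f%%  %d events vs reference\n",
                h$label, h$genome, 100 * h$freq, nrow(h$edits_vs_ref)))
  invisible(x)
}

# encode an edit table the way call tables encode events
edits_as_calls <- function(et, region) {
  if (nrow(et) == 0L)
    return(data.table::data.table(rp = integer(), type = character(),
                                  ref = character(), alt = character()))
  data.table::data.table(
    rp = internal_to_rp(region, et$pos),
    type = ifelse(et$type == "snp", "snp", "indel"),
    ref = et$ref,
    alt = ifelse(et$type == "snp", et$alt,
          ifelse(et$type == "del", paste0("-", et$ref), paste0("+", et$alt))))
}

#' Expected variant table from a haplotype set
#'
#' The analytically expected combined report: every haplotype event with
#' the summed relative frequency of the haplotypes carrying it.
#'
#' @param hapset a `haplotype_set`.
#' @param region the [reference_region()] (B backbone).
#' @return data.table: rp, type, ref, alt, freq_pct.
#' @export
truth_variants <- function(hapset, region) {
  rows <- data.table::rbindlist(lapply(hapset$haps, function(h) {
    d <- edits_as_calls(h$edits_vs_ref, region)
    d[, freq := h$freq]
    d
  }))
  if (nrow(rows) == 0L)
    return(data.table::data.table(rp = integer(), type = character(),
                                  ref = character(), alt = character(),
                                  freq_pct = numeric()))
  out <- rows[, .(freq_pct = 100 * sum(freq)), by = .(rp, type, ref, alt)]
  data.table::setorder(out, rp, type, alt)
  out[]
}

#' Expected per-position non-reference fraction
#'
#' SNP and deletion events contribute their haplotype frequency at every
#' reference position they cover; insertions do not alter base counts at
#' their anchor and are reported only in [truth_variants()].
#'
#' @param hapset a `haplotype_set`.
#' @param region the [reference_region()].
#' @return data.table: rp, nonref (fraction in [0,1]) for positions with a
#'   non-zero expectation.
#' @export
truth_fractions <- function(hapset, region) {
  n <- nchar(region$sequence)
  frac <- numeric(n)
  for (h in hapset$haps) {
    et <- h$edits_vs_ref
    if (nrow(et) == 0L) next
    for (i in seq_len(nrow(et))) {
      if (et$type[i] == "snp") {
        frac[et$pos[i]] <- frac[et$pos[i]] + h$freq
      } else if (et$type[i] == "del") {
        span <- et$pos[i]:(et$pos[i] + nchar(et$ref[i]) - 1L)
        frac[span] <- frac[span] + h$freq
      }
    }
  }
  idx <- which(frac > 0)
  data.table::data.table(rp = internal_to_rp(region, idx), nonref = frac[idx])
}

#' Assemble the full truth set
#' @param hapset a `haplotype_set`.
#' @param region the [reference_region()].
#' @return list: haplotypes (table), variants, fractions, introns.
#' @export
truth_set <- function(hapset, region) {
  hap_tab <- data.table::rbindlist(lapply(hapset$haps, function(h)
    data.table::data.table(label = h$label, genome = h$genome,
                           freq_pct = 100 * h$freq,
                           events = edits_to_string(
                             data.table::copy(h$edits_vs_ref)[, pos := internal_to_rp(region, pos)]),
                           length = nchar(h$seq))))
  introns <- data.table::rbindlist(lapply(hapset$haps, function(h) {
    if (is.null(h$introns) || NROW(h$introns) == 0L) return(NULL)
    d <- data.table::as.data.table(h$introns)
    d[, label := h$label]
    d
  }), fill = TRUE)
  list(haplotypes = hap_tab, variants = truth_variants(hapset, region),
       fractions = truth_fractions(hapset, region), introns = introns)
}

#' Write a truth set to disk (TSV + JSON)
#' @param truth from [truth_set()].
#' @param dir output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$haplotypes, file.path(dir, "truth_haplotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$variants, file.path(dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(fractions = truth$fractions,
                            introns = truth$introns),
                       file.path(dir, "truth.json"), dataframe = "columns",
                       digits = NA)
  invisible(dir)
}

#' 454-style error model
#'
#' Indel errors concentrate in homopolymer runs: the per-base indel
#' probability is `indel_base_rate * multiplier^(run_length - 1)`, capped
#' at 0.5.  Qualities follow a linear positional profile on the Phred
#' scale, clipped to [2, 40].
#'
#' @param substitution_rate per-base substitution error rate.
#' @param indel_base_rate homopolymer indel base rate.
#' @param multiplier per-extra-repeat multiplier.
#' @param quality_start,quality_end mean Phred at read start/end.
#' @param quality_sd spread of the quality profile.
#' @export
error_model <- function(substitution_rate = 1e-3, indel_base_rate = 5e-4,
                        multiplier = 3, quality_start = 37, quality_end = 28,
                        quality_sd = 2) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            indel_base_rate >= 0, indel_base_rate <= 1, multiplier >= 1)
  structure(list(substitution_rate = substitution_rate,
                 indel_base_rate = indel_base_rate, multiplier = multiplier,
                 quality_start = quality_start, quality_end = quality_end,
                 quality_sd = quality_sd),
            class = "error_model")
}

inject_errors <- function(seq, em) {
  if (em$substitution_rate == 0 && em$indel_base_rate == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (em$substitution_rate > 0) {
    hit <- which(stats::runif(n) < em$substitution_rate)
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  out <- ch
  if (em$indel_base_rate > 0) {
    r <- rle(ch)
    runlen <- rep(r$lengths, r$lengths)
    p <- pmin(0.5, em$indel_base_rate * em$multiplier^(runlen - 1))
    hit <- which(stats::runif(n) < p)
    for (i in hit)
      out[i] <- if (stats::runif(1) < 0.5) paste0(ch[i], ch[i]) else ""
  }
  paste(out, collapse = "")
}

sim_qualities <- function(len, em) {
  if (len == 0L) return("")
  frac <- if (len == 1L) 0 else (seq_len(len) - 1L) / (len - 1L)
  mu <- em$quality_start + frac * (em$quality_end - em$quality_start)
  q <- pmin(40L, pmax(2L, as.integer(round(stats::rnorm(len, mu, em$quality_sd)))))
  phred_string(q)
}

# truncated-normal read length via inverse CDF
rtrunc_len <- function(n, mean, sd, lo, hi) {
  a <- stats::pnorm(lo, mean, sd); b <- stats::pnorm(hi, mean, sd)
  as.integer(round(stats::qnorm(stats::runif(n, a, b), mean, sd)))
}

#' Sample reads from a haplotype set
#'
#' Reads are drawn multinomially by haplotype frequency.  With
#' `anchored = TRUE` (amplicon-style) each read starts at one end of the
#' template on a random strand, emulating primer-anchored 454 amplicon
#' reads; otherwise start positions are uniform.
#'
#' @param hapset a `haplotype_set` (or list of haplotypes with seq/freq).
#' @param depth number of reads.
#' @param em an [error_model()].
#' @param seed integer seed.
#' @param read_len_mean,read_len_sd,read_len_min,read_len_max read-length
#'   distribution (truncated normal; lengths are additionally capped at
#'   the template length).
#' @param lib library name used in read identifiers.
#' @param anchored amplicon-style anchoring (see above).
#' @return list: `reads` (a [fastq_set]; identifiers encode
#'   lib:serial:source-haplotype) and `sources` (data.table read_id,
#'   label).
#' @export
sample_reads <- function(hapset, depth, em = error_model(), seed = 1L,
                         read_len_mean = 420, read_len_sd = 60,
                         read_len_min = 100L, read_len_max = 600L,
                         lib = "lib", anchored = TRUE) {
  stopifnot(depth >= 0L)
  haps <- hapset$haps
  set.seed(seed)
  if (depth == 0L)
    return(list(reads = fastq_set(),
                sources = data.table::data.table(read_id = character(),
                                                 label = character())))
  freqs <- vapply(haps, function(h) h$freq, 1)
  src <- sample(seq_along(haps), depth, replace = TRUE, prob = freqs)
  lens <- rtrunc_len(depth, read_len_mean, read_len_sd, read_len_min, read_len_max)
  ids <- character(depth); seqs <- character(depth); quals <- character(depth)
  labels <- vapply(haps, function(h) h$label, "")
  for (i in seq_len(depth)) {
    tpl <- haps[[src[i]]]$seq
    L <- nchar(tpl)
    len <- min(lens[i], L)
    if (anchored) {
      fwd <- stats::runif(1) < 0.5
      raw <- if (fwd) substr(tpl, 1L, len) else substr(tpl, L - len + 1L, L)
      if (!fwd) raw <- revcomp(raw)
    } else {
      start <- sample.int(L - len + 1L, 1L)
      raw <- substr(tpl, start, start + len - 1L)
    }
    raw <- inject_errors(raw, em)
    ids[i] <- sprintf("%s:%06d:%s", lib, i, labels[src[i]])
    seqs[i] <- raw
    quals[i] <- sim_qualities(nchar(raw), em)
  }
  list(reads = fastq_set(ids, seqs, quals),
       sources = data.table::data.table(read_id = ids, label = labels[src]))
}

#' Sample amplicon reads for every amplicon of a pool
#'
#' Extracts each haplotype's subsequence over each amplicon interval
#' (projected through the haplotype's edit list) and samples
#' primer-anchored reads at the given per-amplicon depth.
#'
#' @param hapset a `haplotype_set`.
#' @param region the [reference_region()].
#' @param amplicons an [amplicon_set()].
#' @param depth reads per amplicon.
#' @param em an [error_model()].
#' @param seed integer seed.
#' @param lib library name.
#' @param ... passed to [sample_reads()].
#' @return list as in [sample_reads()].
#' @export
amplicon_pool <- function(hapset, region, amplicons, depth,
                          em = error_model(), seed = 1L, lib = "lib", ...) {
  out_r <- list(); out_s <- list()
  for (k in seq_len(nrow(amplicons))) {
    s <- rp_to_internal(region, amplicons$rp_start[k])
    e <- rp_to_internal(region, amplicons$rp_end[k])
    lf <- nchar(amplicons$fwd[k]); lr <- nchar(amplicons$rev[k])
    sub <- hapset
    sub$haps <- lapply(hapset$haps, function(h) {
      # primer synthesis overrides template variation at both product ends
      iv <- map_ref_interval(h$edits_vs_ref, s + lf, e - lr)
      h$seq <- paste0(substr(region$sequence, s, s + lf - 1L),
                      substr(h$seq, iv[1L], iv[2L]),
                      substr(region$sequence, e - lr + 1L, e))
      h
    })
    res <- sample_reads(sub, depth, em, seed = seed + 97L * k,
                        lib = paste0(lib, ":", gsub("/", "", amplicons$pair_name[k])),
                        anchored = TRUE, ...)
    out_r[[k]] <- res$reads
    out_s[[k]] <- res$sources
  }
  reads <- fastq_set(unlist(lapply(out_r, `[[`, "id")),
                     unlist(lapply(out_r, `[[`, "seq")),
                     unlist(lapply(out_r, `[[`, "qual")))
  list(reads = reads, sources = data.table::rbindlist(out_s))
}
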
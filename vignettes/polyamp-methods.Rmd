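---
title: "Deep amplicon analysis of homeologous gene families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep amplicon analysis of homeologous gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Hexaploid wheat carries three homeologous copies (A, B, D subgenomes) of
most genes. When a gene family such as the DELLA dwarfing genes
(*Rht-A1/B1/D1*) is amplified with primers designed against conserved
regions, all three copies — and every allelic variant of each copy —
co-amplify. Deep sequencing of the pooled product turns allele discovery
into a deconvolution problem: each library is a mixture of haplotypes at
unknown relative frequencies on the order of 0.1%–100%, aligned against a
single reference (conventionally a B-genome allele). `polyamp` implements
that analysis as a tested pipeline: quality trimming, reference-guided
alignment and pileup, frequency-threshold SNP/indel calling with
cross-library confirmation of rare variants, haplotype ("amplicon
variant") reconstruction with genome/allele assignment, protein-consequence
annotation, putative spliceosomal-intron detection, and two-point linkage
placement of a variant marker on a doubled-haploid (DH) map.

Every stage is exercised end to end on a synthetic hexaploid pool with a
recorded truth set, so the pipeline's claims are testable without any
download.

## Quality trimming

The trimmer is the standard limit-based (modified-Mott) algorithm: base
$i$ scores $\mathrm{limit} - 10^{-Q_i/10}$ and the kept subread is the
contiguous window with the maximal score sum, ties resolved to the
smallest start and then the longest window. The default limit of 0.05
reproduces the qualitative behaviour expected of good 454 amplicon
libraries (Phred 20–40): high-quality reads pass untouched. Terminal runs
of more than `max_ambiguous` (default 4) ambiguous bases are cut from
either end; the contract is checked against an exhaustive $O(n^2)$ window
search. There is no published minimum retained length for this protocol;
the default of 50 nt is our choice and is configurable.

## Alignment, end clipping and pileups

Reads are aligned end-to-end (read-global, reference-ends-free) under
affine gap scoring (match +1, mismatch −2, gap open 4, gap extend 1 per
base), in the better of the two orientations; indels are left-aligned
within repeat runs so that one event aggregates at a single reference
position (RP). When amplicon definitions are supplied, reads are first
demultiplexed by primer prefix — fixing strand and restricting the
dynamic programming to the amplicon window — which is both how amplicon
pipelines work and an order-of-magnitude speedup.

Two departures from a naive aligner matter here:

* **Identity threshold 0.72.** Identity is matches divided by all aligned
  columns, including gap columns. A read carrying a 72-nt retained-intron
  insertion on a ~95%-identity homeolog background has identity ≈ 0.78;
  a threshold of 0.80 (a natural first guess) silently discards exactly
  the variant class the pipeline exists to find. The default is therefore
  0.72, still comfortably above off-target product.
* **Anchored end clipping.** An amplicon read whose end falls *inside* a
  long insertion has no homologous sequence for that end; pattern-global
  alignment then smears the unmatchable tail across the reference,
  creating coherent artifact events. Alignment ends are kept only from
  the first/last run of 12 consecutive matched columns; clipped lengths
  are reported per read (`clip5`, `clip3`). Since amplicon reads begin
  with primer-identical bases, correctly placed reads are not clipped.

Pileup columns count A/C/G/T/N and deletion per covered RP; insertion
events are anchored after their RP. Bases under a primer at a read's end
are masked out of the counts: primer synthesis overrides template
variation, so those bases carry no information about the template.
Positions with zero coverage are omitted.

## Variant calling

An event is called in a library when depth ≥ 40 and the non-reference
fraction ≥ 20% (inclusive on both bounds). Sub-threshold events are
candidates and are rescued only by the cross-library rule: present
(frequency > 0) in at least two *other* libraries with at least 5% in one
of them. "Present" is evaluated only over libraries that cover the
position; with fewer than three libraries the rule is undefined and
candidates are rejected. Indels are treated with the same thresholds as
SNPs — the source protocol states the rule for SNPs and reports indels in
the same table; the uniform reading is the minimal consistent one. The
combined report has one row per (RP, type, ref, alt) with per-library
frequency, depth and status; summary counts split positions into
SNP-only, indel-only and both.

## Haplotype (amplicon variant) reconstruction

Reads covering ≥ 95% of an amplicon interval vote; each read's event
string is its alignment events restricted to *accepted* variant events
(called or cross-confirmed). Reads sharing an event string form one
amplicon variant; its relative frequency is its share of full-span reads,
and its consensus is the reference interval with the events applied —
i.e. mismatches that did not survive calling are treated as sequencing
error and take the reference base.

One correction matters for insertion haplotypes: their product is longer,
so reads of a given length cover less of the reference and the plain
full-span rule under-counts exactly the retained-intron variants. Reads
whose covered reference plus inserted bases meet the span threshold are
therefore rescued and assigned to the unique variant whose event string
is consistent with theirs over the covered range; without this, a 72-nt
insertion haplotype at 10% recovers at roughly half its true frequency
under the default read-length model.

Variants with fewer than 2 supporting
reads are merged into the nearest larger variant by event-set symmetric
difference (2 is the smallest support that excludes singleton errors
while keeping 0.1%-scale variants in 10^4-read libraries). Genome/allele
assignment aligns each consensus globally against a panel of reference
alleles and takes the maximum-identity entry; exact ties go to the higher
score then lexicographic name and are flagged ambiguous when separated by
less than 1 identity point.

## Protein consequences

The CDS frame is anchored at the reference start codon. SNPs are
classified synonymous / missense / nonsense from the genetic code, with
the codon position reported as $((\mathrm{cds\ nt} - 1) \bmod 3) + 1$.
Motifs are located on the reference protein either by literal string
(TVHYNP) or by configured residue interval; the DELLA region defaults to
residues 40–75 and the GRAS domain to 200–620 — these intervals come from
the deposited allele annotations of the DELLA literature, not from any
printed coordinate, and should be overridden for other gene families.
Variant-level diffs translate the consensus in the reference frame and
report premature stops (truncation codon), in-frame single-residue
indels, and frameshifts.

## Putative intron detection

A frame disruption is a net indel not divisible by 3, or a premature
stop. For a disrupted variant, every interval of length 4–200 nt on its
consensus whose removal (i) restores the reading frame and (ii) leaves no
premature stop is a splice candidate. Candidates are ranked by
*reference-codon recovery*: the fraction of the amplicon's reference
codons that the spliced sequence reproduces in frame, with codon
positions projected through the variant's own event list. This single
score penalises leftover frameshifted stretches, leftover insertion
bases and deleted reference codons symmetrically — simpler heuristics
fail: ranking canonical boundaries first lets chance GT..AG 5-mers beat
a genuine non-canonical retained segment, ranking by fewest deleted
residues is fooled when the variant carries an unrelated in-frame indel,
and raw DNA identity rewards large "remove anything and the same from
the reference" intervals. Equal scores break canonical (GT..AG) before
non-canonical — preserving the convention that a canonical interval
outranks a non-canonical one of equal length — then leftmost, then
shortest. The pipeline drops candidates recovering less than 70% of
reference codons, so a point nonsense mutation is not "explained" by an
arbitrary interval removal.

Two caveats are documented rather than hidden. First, local repeats can
make several shifted intervals produce equally reference-consistent
spliced products; the scanner then reports the leftmost representative
(the same convention as indel left-alignment), whose boundary
dinucleotides may differ from the "intended" representation. Second, the
exhaustive single-interval scan resolves one retained intron per
disrupted variant; a variant carrying two introns at once is handled by
`splice_and_translate()` on known intervals, not by blind scanning. The
in-silico splice of a clean planted intron restores the reference
protein exactly, which the tests assert.

## Two-point linkage placement

DH lines are fully homozygous, so the recombination fraction between two
markers is the recombinant share of lines scored at both (missing calls
excluded pairwise; repulsion-phase coding folded back below 0.5). LOD is
the base-10 binomial likelihood ratio against r = 0.5, significance the
one-sided binomial tail, and map distance Kosambi by default (the wheat
mapping convention; Haldane available). `place_marker()` tests a new
marker against every map marker and returns the closest significant
(p < 0.001 by default) linkage. At the study scale (n = 180, r ≈ 0.024)
placement lands within 0.5–5 cM of the true partner in ≈96% of
replicates — the acceptance test checks exactly that on 200 simulated
populations.

## The synthetic world

`make_panel()` derives three backbones from a common ancestor: each
genome receives independent substitutions at rate divergence/2 (so
pairwise identity ≈ 1 − divergence; 0.95 by default, checked against an
edit-distance oracle within ±0.01) and two short indels — free 1–3-nt
indels in the UTR, 3-nt in-frame indels in the CDS — with backbones
regenerated until stop-free, because real homeologs of a functional gene
family are in frame. The B backbone doubles as the pipeline reference,
and every haplotype carries an exact edit list against it, so truth
(per-position non-reference fractions, the expected variant table) is
computed analytically — never via an aligner.

The demonstration pool mirrors the biology the pipeline targets: a clean
B "type" haplotype at 60%; an A haplotype at 30% with five SNPs (one
creating a stop inside the DELLA interval), one full-codon deletion and a
single-base deletion leaving a 5-nt AC..AT retained segment; and a D
haplotype at 10% carrying a 72-nt GT..AG insertion with an in-frame stop.
The 10% haplotype deliberately sits *below* the 20% call threshold so the
cross-library confirmation path is exercised, not just the direct one.
Planting sites are chosen deterministically from the panel (first
conforming site scans), with junction-equivalent repeat contexts
rejected; an unlucky panel triggers a bounded, seeded re-draw.

Reads are primer-anchored on a random strand with truncated-normal
lengths (mean 420, sd 60, bounds [100, 600], capped at the product
length — amplicon reads routinely run the full product, and haplotype
grouping needs those full-span reads). Product ends carry the primer
(= reference) sequence, as real amplicons do. The error model is
454-flavoured: per-base substitutions, homopolymer indels with
probability $\mathrm{rate} \times \mathrm{multiplier}^{\mathrm{run}-1}$
capped at 0.5, and a linear positional Phred profile (37 → 28, sd 2,
clipped to [2, 40]). What the generator does *not* emulate: flowgram
noise, chimeras/PCR duplicates, or coverage unevenness between amplicons
— a green end-to-end test therefore establishes the logic of the
pipeline, not robustness to every 454 artifact.

## Numerical and degenerate-input choices

Frequencies are carried as exact fractions and rounded only on output.
Threshold comparisons are inclusive (exactly 20% at exactly depth 40 is
called). Zero-coverage positions are omitted, empty libraries produce
empty-but-valid stages, and depth-0 simulation yields a valid empty
FASTQ. All randomness flows from a single integer seed per generator
call; identical seeds give byte-identical FASTQ output.

## Known limitations

* Statistical phasing of partially overlapping reads is out of scope;
  only full-span reads vote for haplotypes.
* The intron scanner's identity ranking assumes the reference is the
  correct backbone for the disrupted variant; highly diverged paralogs
  would need a per-genome reference.
* Consequence annotation is splice-naive by design: introns are detected
  first, and translation of a disrupted variant is meaningful only after
  `splice_and_translate()`.
* With fewer than three libraries the rare-variant rule cannot run, and
  sub-threshold variants are lost; this matches the protocol's intent but
  surprises on small designs.
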
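Package: polyamp
Title: Deep Amplicon Variant and Haplotype Analysis for Polyploid Gene Families
Version: 0.1.0
Authors@R:
    person("EMAI", "Bioinformatics", email = "devnull@example.org", role = c("aut", "cre"))
Description: Tools for analysing pooled deep-amplicon sequencing of multi-copy
    (homeologous) gene families in polyploid genomes. Provides quality trimming
    of long amplicon reads, reference-guided semi-global alignment and pileup
    construction tolerant of homeolog divergence, frequency-threshold SNP and
    indel calling with cross-library confirmation of rare variants, haplotype
    (amplicon variant) reconstruction from linked variants with relative
    frequency quantification and allele/genome assignment, protein-consequence
    annotation including premature stop detection and motif localisation,
    detection of putative spliceosomal introns from reading-frame disruption
    and splice-boundary dinucleotides, and two-point linkage placement of a
    variant marker on a doubled-haploid map. A synthetic hexaploid
    amplicon-pool generator with a recorded truth set makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
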
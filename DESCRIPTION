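Package: pansvkit
Title: Pan-Genome Structural-Variant Population Genetics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pan-genome presence/absence variation (PAV)
    and structural-variant (SV) population genetics in livestock cohorts.
    Calls gene presence from exon coverage tables and fits pan/core growth
    curves; scans for SVs under domestication or improvement selection by
    intersecting Fisher's exact tests with top-percentile Weir-Cockerham
    F_ST; quantifies transposable-element/SV co-occurrence and intact-TE
    derived SVs; dates LTR retrotransposon insertions from LTR-LTR
    divergence (T = K/(2r)); computes windowed diversity statistics (pi,
    Tajima's D, windowed F_ST) and single-marker association with marker-R2
    variance partitioning. Includes a fully seeded synthetic-cohort
    generator emitting standard formats (VCF, BED, GFF3, FASTA, TSV) so
    every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    rtracklayer,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
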
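Package: varikit
Title: Downstream Analysis of Crop Re-Sequencing Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable implementation of the downstream analysis of a
    whole-genome re-sequencing comparison between two crop genotypes: acceptance
    filtering of candidate SNP and structural-variant calls, codon-level effect
    annotation with large-effect classes (premature stop, start loss, splice
    disruption, stop loss), transition/transversion and indel size-class
    statistics, window-based variant density scans, per-Pfam chi-square
    enrichment of nonsynonymous versus synonymous SNPs, design of PCR length
    markers from insertion/deletion variants, confirmation of inversions from
    contig alignments by plus/reverse strand coverage, and fine mapping of a
    recessive locus in an F2 population by the recombinant-class method. A
    synthetic-data module generates a miniature annotated genome with spiked
    variants of every class, inversion-bearing contigs and a Mendelian F2
    population so every stage can be exercised end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    jsonlite,
    optparse
Config/testthat/edition: 3
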
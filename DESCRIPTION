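Package: repeatforge
Title: Transposable Element Library Curation, Classification and
    Evolutionary Analysis with Synthetic Benchmarks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale reimplementation of a repeatome analysis
    pipeline for transposable elements (TEs): curation of consensus
    libraries from genomic hit tables (coverage-based trimming and
    splitting, 80/80 redundancy clustering, copy-support filtering,
    tandem-repeat screening, seed-alignment extension), subclass and
    superfamily classification by a two-of-three vote over nucleotide
    homology, translated-protein homology and terminal-inverted-repeat
    structure (including MITE calling), Kimura 2-parameter divergence
    landscapes with optional CpG adjustment, TE density across gene
    anatomy (TSS flanks, UTRs, exons, introns, intergenic space), and
    family-level differential expression with a negative-binomial Wald
    test. A synthetic-genome simulator plants TE families at controlled
    divergence, copy number and truncation, together with gene models
    and count matrices, so that every stage is testable against known
    truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomeInfoDb,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, Transcriptomics, Annotation, Alignment, Software
RoxygenNote: 7.3.3
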
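Package: ltrscape
Title: Annotation, Dating and Genomic Distribution Analysis of LTR Retrotransposons
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for annotating long terminal repeat (LTR) retrotransposons
    in assembled genomes by combining homology evidence, de novo structural
    detection of paired LTRs, and secondary homology expansion from
    structurally intact elements. Includes lineage classification from
    nucleotide and protein domain evidence, molecular-clock insertion dating
    from LTR-LTR divergence, and genomic distribution statistics: chromosome
    density models, cluster calling with a Monte-Carlo random-integration
    null, distance-to-gene enrichment tests, and expression-completeness
    classification. A synthetic genome simulator with planted elements and a
    truth table supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Annotation, Genetics, SequenceMatching, Transcriptomics
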
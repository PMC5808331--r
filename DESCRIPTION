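Package: lncfam
Title: Discovery of Long Non-Coding RNA Gene Families from Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering families of long non-coding RNA
    (lncRNA) genes in an annotated genome. Builds a transcript catalog from
    GFF3+FASTA or GenBank flat-file annotations, selects representative
    isoforms per locus, runs all-vs-all nucleotide homology search with a
    built-in seed-and-extend local aligner (or imports external BLASTN
    tabular output), applies a filter cascade (ribosomal RNA removal,
    self-locus removal, minimum significant match length), classifies
    matches by subject category and species, clusters loci into gene
    families as connected components of the homology graph, screens
    families against a transposable-element library to remove spurious
    TE-driven groupings, and summarises the family size and degree spectra.
    Also ingests rMATS-style differential-splicing event tables, applies
    p-value and FDR significance filters, intersects significant locus sets
    across comparisons, and tallies events on lncRNA loci. Includes a
    synthetic-data generator that plants gene families, TE decoys,
    ribosomal loci, coding-homology sharing and significant splicing events
    with a machine-readable truth manifest, so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
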
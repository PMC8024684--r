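Package: mvgkit
Title: Defining Phage Groups from Metagenomic Viral Genomes and Mapping
    Their Ocean Biogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for defining a phage group around a
    reference isolate genome and charting its distribution across viromes.
    Implements ORF calling on circular phage genomes, protein and
    nucleotide local alignment (Smith-Waterman and seeded banded
    extension), Markov clustering of protein similarity graphs into
    orthologous groups, shared-gene-content membership classification,
    fragment-based average nucleotide identity with single-linkage
    dereplication, neighbor-joining marker and whole-proteome phylogenies
    with bootstrap support, and viromic read recruitment with KPKG
    abundance normalization and breadth-of-coverage filtering. A
    synthetic-data module generates phage genomes, diverged genome panels
    and read sets with planted truth so every stage can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    igraph,
    ape,
    phangorn,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
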
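Package: genoclust
Title: Graph-Based Genome Clustering for Species Delimitation from
    Identity Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Delimits prokaryotic genospecies from overall genome-related
    index (OGRI) matrices such as average nucleotide identity (ANI),
    alignment coverage and digital DNA-DNA hybridization (dDDH).  Pairwise
    matrices are symmetrized by pair averaging, binarized against
    user-chosen cut-offs (e.g. ANI >= 95%), combined across matrices by
    logical consensus, and turned into an undirected graph whose maximal
    cliques and connected components are candidate species clusters.
    Taxonomy-aware filters retain clusters that merge several binomial
    names (candidate synonyms) or split genomes sharing one name
    (candidate misidentifications).  Also provides genome quality
    screening on completeness/redundancy tables, gap-aware 16S rRNA
    pairwise identity, and a synthetic block-matrix generator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr,
    withr
Config/testthat/edition: 3
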
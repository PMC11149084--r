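Package: kmersig
Title: Species Identification in Metagenomes via a Genome-Id Bloom Filter and
    Coverage Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts which bacterial species are present in a shotgun
    metagenomic sample. Reference genomes are indexed in a modified Bloom
    filter whose entries store genome identifiers (with an explicit "dirty"
    sentinel for k-mers shared between genomes); reads are assigned to
    genomes by unanimity votes of their k-mers and a strict majority rule,
    with an optional mean-Phred k-mer quality gate; putative species are
    then screened by one-dimensional K-means clustering of approximate
    genomic coverages, discarding the lowest-coverage cluster as false
    positives. Includes a seeded community simulator (genomes, error-bearing
    reads, ground truth) and precision/recall/F1 scoring, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
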
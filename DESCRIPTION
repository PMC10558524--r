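Package: metahic
Title: Normalization and Genome Binning for Metagenomic Hi-C Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing metagenomic Hi-C (metaHi-C) experiments:
    construction of a contig-by-contig proximity-ligation contact matrix from
    filtered read alignments, two-stage negative-binomial normalization of
    systematic biases (restriction-site count, contig length and coverage, the
    latter represented through within-contig ligation counts), percentile-based
    removal of spurious inter-species contacts, and clustering of contigs into
    metagenome-assembled genomes by Leiden community detection under the
    Reichardt-Bornholdt Potts modularity with an automatically tuned resolution
    parameter. Includes discard-retain curve and clustering-agreement metrics
    for benchmarking, and a synthetic metaHi-C community generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    Rsamtools,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust
Config/testthat/edition: 3
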
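Package: itsprofiler
Title: Profiling, Pseudogene Screening and Phylogeny of the Plant
    ITS1-5.8S-ITS2 Region
Version: 0.1.0
Authors@R:
    person("ITS", "Profiler Developers", email = "itsprofiler@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the nuclear ribosomal ITS1-5.8S-ITS2
    region in plants: sub-region delimitation against an annotated
    reference, per-region length and GC statistics, pairwise identity
    matrices and nucleotide diversity, conserved 5.8S motif scanning,
    secondary-structure topology checks for ITS2 and 5.8S, combined
    putative-pseudogene classification, collapsing of clone libraries
    into consensus ITS types, Jukes-Cantor neighbour-joining phylogeny
    with nonparametric bootstrap and midpoint rooting, genome-constitution
    assignment for hybrids, read-depth profiling, and a seeded synthetic
    data generator that emulates divergent functional and pseudogenised
    ITS paralogs, clone libraries and shotgun reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    phangorn,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
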
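Package: microprofiler
Title: Desk-Scale Taxonomic and Functional Profiling of Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for microbial community analysis from
    16S rRNA amplicon or shotgun metagenomic reads: profile-based 16S fragment
    extraction, alignment-based OTU assignment at the 97 percent identity
    level, 16S copy-number calibration of relative abundances, taxonomy
    roll-up, nearest-sequenced-taxon functional (KO and pathway) prediction
    with NSTI reliability scores, alpha- and beta-diversity statistics
    including a phylogeny-aware community similarity, PERMANOVA-style
    permutation tests, biomarker screening with random-forest ranking,
    co-occurrence network construction, and a synthetic reference-database
    and read simulator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    ranger,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
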
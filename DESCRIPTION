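Package: magpop
Title: Population Statistics for Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies sequence-discrete microbial populations from
    metagenomic read recruitment. Implements truncated average sequencing
    depth (TAD), single-copy marker-gene (rpoB-style) normalization of
    genome depth to community relative abundance, recruitment plots with
    automated detection of the population identity cutoff, read-based
    average nucleotide identity (ANIr) as an intra-population diversity
    proxy, MinHash-based genome dereplication with
    completeness/contamination quality scoring, detection/prevalence and
    size-fraction enrichment summaries, and a synthetic-community read
    simulator with complete ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
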
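Package: wgdpop
Title: Whole-Genome Duplication Profiling and SNP-Based Population Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects whole-genome duplication from intragenomic colinear gene
    blocks and the distribution of fourfold-degenerate transversion (4DTv)
    distances between paralog pairs, and assesses population diversity and
    structure from filtered SNP genotypes: gene diversity, polymorphism
    information content, observed heterozygosity and minor allele frequency;
    covariance-method principal components; maximum-likelihood admixture with
    Evanno delta-K model selection. Includes seeded simulators for duplicated
    genomes and admixed genotype panels so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
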
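Package: lodemap
Title: Linkage-Disequilibrium-Based Placement of Unmapped Markers on Genetic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Assigns unmapped biallelic SNP markers to linkage groups and
    estimates their centimorgan positions on an existing sparse genetic map
    using multi-point linkage disequilibrium (LD) with mapped anchor markers
    (a locus-ordering-by-disequilibrium approach). Includes pairwise r^2
    estimation from 0/1/2 genotype allele counts with pairwise-complete
    handling of missing calls, intra-chromosomal LD-decay profiling with
    LOESS smoothing, k-fold masking cross-validation with efficiency,
    accuracy and precision metrics, an r^2-threshold sweep, and a
    forward-in-time breeding-population simulator (few founders, Haldane
    recombination) that provides ground-truth maps and genotypes for
    testing. Readers and writers for delimited genotype matrices, VCF
    genotypes under a pseudo-diploid collapse, and genetic-map tables are
    provided, along with a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
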
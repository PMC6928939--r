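Package: qtmod
Title: Quantitative-Trait Module Analysis of Subcortical Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for module-based quantitative-trait
    genetic analysis of subcortical brain structure volumes. Provides genotype
    quality control (call rates, sex check, identity-by-descent relatedness,
    Hardy-Weinberg exact test, minor-allele-frequency filter, windowed LD
    pruning), intracranial-volume normalization of regional volumes,
    correlation-based hierarchical clustering of structures into modules,
    covariate-adjusted genome-wide association of module volumes, an anchored
    SNP-by-SNP interaction scan, and degree-based selection of interactive
    loci. A synthetic-data generator with planted ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
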
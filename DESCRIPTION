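Package: mkmicrobiome
Title: Multi-Kingdom Root and Leaf Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of bacterial and fungal amplicon count
    tables from replicated host accessions grown in a common environment.
    Implements depth-corrected differential enrichment between organs (Poisson
    generalized linear models with log-read offsets), alpha and beta diversity
    modelling with mixed models and best linear unbiased predictors (BLUPs),
    cross-kingdom Pearson correlation networks with centrality summaries,
    BLUP-based principal component ordination with Procrustes comparison,
    nested-subset permutation tests for host-genotype clustering, SNP-kinship
    heritability by spectral restricted maximum likelihood, mixed-model
    genome-wide association with Cholesky-permutation significance thresholds,
    and gene-ontology tail enrichment with Storey q-values.  A synthetic-data
    generator emulating the replicated-accession, two-kingdom study design is
    included so that every stage of the pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    generics,
    ggplot2,
    lme4,
    igraph,
    vegan,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr
Config/testthat/edition: 3
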
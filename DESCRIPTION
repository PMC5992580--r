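Package: lofburden
Title: Loss-of-Function Variant Prioritisation and Gene-Set Burden Testing in Family Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritises rare germline loss-of-function variants in small
    family cohorts (such as hereditary diffuse gastric cancer families without
    CDH1 mutations) and burden-tests candidate gene sets against a reference
    control panel. Filters VEP-annotated multi-sample VCFs to rare
    protein-affecting variants carried by affected individuals, collapses
    variants to genes, clusters candidate genes on a physical-interaction
    network, assigns Gene Ontology terms by hypergeometric over-representation
    with Bonferroni correction, tests term-level loss-of-function burden with
    one-tailed Fisher exact tests using family-deduplicated counts, checks
    within-family segregation, and aggregates published per-proband carrier
    records for cross-study carrier enrichment analysis. Ships a seeded
    synthetic-cohort generator (pedigree-aware Mendelian genotypes, planted
    interaction cluster and gene-set signal) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
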
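# lofburden

Loss-of-function variant prioritisation and gene-set burden testing for
small family cancer cohorts.

## The problem

Some hereditary cancer syndromes — the motivating case is hereditary
diffuse gastric cancer in families without a pathogenic *CDH1* variant —
are too rare for association studies: a typical whole-exome cohort is a
few dozen individuals from a couple of dozen families. `lofburden`
implements the prioritisation strategy used in that setting:

1. **Filter** a VEP-annotated multi-sample VCF to rare
   (reference-panel allele frequency < 0.05), protein-affecting variants
   (loss-of-function; SIFT-deleterious *and* PolyPhen-damaging missense;
   in-frame indels) carried by at least one affected individual.
2. **Collapse** variants to genes; keep genes with at least one
   loss-of-function (LoF) variant; drop the top 1% hypervariable genes
   (mucin/HLA-like genes that tolerate many rare variants).
3. **Cluster** candidate genes on a physical-interaction network
   (connected components of five or more genes).
4. **Assign** each cluster a Gene Ontology term by exact hypergeometric
   over-representation with Bonferroni correction, restricted to terms
   annotating 10–200 genes.
5. **Burden-test** each selected term: family-deduplicated LoF counts in
   the cohort versus aggregated LoF allele counts in a control panel, by a
   one-tailed Fisher exact test

   p = P(X ≥ a),  X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b)

   on the table [[a = in-term cases, b = out-of-term cases],
   [c = in-term controls, d = out-of-term controls]].
6. **Check segregation** per family (all sequenced affected members carry;
   unaffected carriers tolerated — incomplete penetrance).
7. **Meta-analyse** published per-proband carrier reports for a gene of
   interest against reference panels (the *PALB2*/*BRCA2*-style
   cross-study comparison).

A seeded synthetic-data module generates the whole input bundle —
annotated VCF, pedigree, interaction network, GMT gene sets, control
counts — with a known planted signal, so every stage is testable offline.

## Worked example

Cross-study carrier meta-analysis from the packaged compilation of
published *PALB2* proband reports (329 probands screened across the
contributing studies):

```r
library(lofburden)

rec <- read_study_records(system.file("extdata", "palb2_study_records.tsv",
                                      package = "lofburden"))
pan <- readr::read_tsv(system.file("extdata", "reference_panels.tsv",
                                   package = "lofburden"), comment = "#")
carrier_meta_analysis(rec, "PALB2", total_probands = 329, panels = pan)
#> Cross-study LoF carrier enrichment: PALB2
#> # A tibble: 2 × 7
#>   gene  carriers n_probands panel            panel_carriers panel_size   p_value
#>   <chr>    <int>      <dbl> <chr>                     <dbl>      <dbl>     <dbl>
#> 1 PALB2        5        329 1000G_EUR                     1        503 0.0384
#> 2 PALB2        5        329 ExAC_NFE_nonTCGA             26      27173 0.0000313
```

Five of 329 probands carry a loss-of-function *PALB2* variant versus 1 of
503 European reference individuals (p ≈ 0.038, one-tailed Fisher) and 26
of 27,173 in the larger panel (p ≈ 3e-05): carriers are significantly
enriched in the families against both panels.

The full pipeline on a seeded synthetic cohort (22 families, 28 affected,
planted 20-gene signal with an 8-gene interaction clique):

```r
cfg <- simulation_config(seed = 1)
paths <- simulate_study_inputs(cfg, "sim_inputs")
s <- run_pipeline(vcf = paths$vcf, ped = paths$ped,
                  network_file = paths$edges, gmt = paths$gmt,
                  control = paths$control, outdir = "run1")
str(s$counts)
#> List of 6
#>  $ variants_input   : int 2821
#>  $ variants_filtered: int 602
#>  $ genes            : int 404
#>  $ candidate_genes  : int 300
#>  $ clusters         : int 1
#>  $ clustered_genes  : int 14
s$selected_terms
#> [1] "TERM_PLANTED"
s$burden[, c("term_id", "case_count", "case_total", "p_value")]
#>        term_id case_count case_total      p_value
#> 1 TERM_PLANTED         63        505 4.285945e-33
```

2,821 annotated variants filter down to 602 candidates in 404 genes; 300
candidate genes yield one interaction cluster, the planted term is
assigned to it, and its LoF burden (63 of 505 family-deduplicated LoF
occurrences in-term, versus 143 of 9,525 control alleles) is strongly
enriched. `run1/` holds one TSV report per stage plus a machine-readable
`summary.json`; results carry broom-style `tidy()`/`glance()` methods and
`autoplot()` figures.

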
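# Small constructors for hand-built fixtures used across the suite.

make_variant <- function(gene, consequence_raw, genotypes,
                         sift = "unknown", polyphen = "unknown",
                         control_af = 0.001, pos = 100L, chrom = "1",
                         ref = "A", alt = "T") {
  tibble::tibble(
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, raw_consequence = consequence_raw,
    consequence = classify_consequence(consequence_raw),
    sift = sift, polyphen = polyphen, control_af = control_af,
    genotypes = list(genotypes)
  )
}

make_variants <- function(...) dplyr::bind_rows(...)

# pedigree from a compact description: named list family -> c(affected ids),
# and optionally unaffected ids
make_ped <- function(affected, unaffected = list()) {
  rows <- list()
  for (fam in union(names(affected), names(unaffected))) {
    ids_a <- affected[[fam]] %||% character()
    ids_u <- unaffected[[fam]] %||% character()
    rows[[fam]] <- tibble::tibble(
      family_id = fam,
      sample_id = c(ids_a, ids_u),
      father = "0", mother = "0", sex = 1L,
      affected = c(rep(TRUE, length(ids_a)), rep(FALSE, length(ids_u)))
    )
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_vcf_path <- function() system.file("extdata", "toy_cohort.vcf", package = "lofburden")
toy_ped_path <- function() system.file("extdata", "toy_cohort.ped", package = "lofburden")
records_path <- function() system.file("extdata", "palb2_study_records.tsv", package = "lofburden")
panels_path <- function() system.file("extdata", "reference_panels.tsv", package = "lofburden")

read_panels <- function() {
  readr::read_tsv(panels_path(), comment = "#", show_col_types = FALSE)
}

# exact brute-force one-tailed Fisher: enumerate every table with the same
# margins, independent of the hypergeometric implementation under test
brute_force_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  table_prob <- function(x) {
    # P(table) with margins fixed = C(r1,x) C(n-r1, c1-x) / C(n, c1)
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  sum(vapply(support[support >= a], table_prob, numeric(1)))
}
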
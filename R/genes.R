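#' Collapse filtered variants into a per-gene summary
#'
#' Partitions variants by gene symbol. Variants with no symbol are grouped
#' under the sentinel `".unassigned"` and flagged so downstream steps can
#' drop them. `variability_count` equals the number of rare protein-affecting
#' variants per gene (the table is meant to be built from the post-filter
#' variant set).
#'
#' @param variants Filtered variant tibble.
#' @return A tibble with one row per gene: `gene`, `n_variants`, `n_lof`,
#'   `lof_flag`, `variability_count`, `unassigned`, and a `variant_ids`
#'   list-column.
#' @export
aggregate_by_gene <- function(variants) {
  if (nrow(variants) == 0) {
    return(tibble::tibble(gene = character(), n_variants = integer(),
                          n_lof = integer(), lof_flag = logical(),
                          variability_count = integer(), unassigned = logical(),
                          variant_ids = list()))
  }
  variants |>
    dplyr::mutate(gene = dplyr::coalesce(.data$gene, ".unassigned")) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      n_lof = sum(.data$consequence == "LOF"),
      variant_ids = list(.data$variant_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lof_flag = .data$n_lof > 0,
      variability_count = .data$n_variants,
      unassigned = .data$gene == ".unassigned"
    ) |>
    dplyr::select("gene", "n_variants", "n_lof", "lof_flag",
                  "variability_count", "unassigned", "variant_ids") |>
    dplyr::arrange(.data$gene)
}

#' Flag hypervariable genes for exclusion
#'
#' Excludes the `ceiling(fraction * G)` genes with the highest counts of
#' rare protein-affecting variants — genes that carry many rare variants in
#' healthy populations and are therefore poor disease candidates. Ties at
#' the cut are resolved by excluding the whole tie group (every gene whose
#' count equals the count of the last-ranked excluded gene); when that
#' expands the exclusion beyond the nominal quota a warning is emitted.
#'
#' @param gene_table Per-gene tibble from [aggregate_by_gene()].
#' @param fraction Fraction of genes to exclude (default 0.01; must be < 1).
#' @return `gene_table` with a logical `hypervariable` column added, sorted
#'   by gene.
#' @export
exclude_hypervariable <- function(gene_table, fraction = 0.01) {
  if (nrow(gene_table) == 0) stop("empty gene table", call. = FALSE)
  if (fraction >= 1 || fraction < 0) {
    stop("fraction must be in [0, 1)", call. = FALSE)
  }
  g <- nrow(gene_table)
  quota <- ceiling(fraction * g)
  if (quota == 0) {
    return(dplyr::arrange(dplyr::mutate(gene_table, hypervariable = FALSE),
                          .data$gene))
  }
  counts <- sort(gene_table$variability_count, decreasing = TRUE)
  cut_count <- counts[quota]
  hyper <- gene_table$variability_count >= cut_count
  if (sum(hyper) > quota) {
    warning("tie at the hypervariable cut: excluding ", sum(hyper),
            " genes (nominal quota ", quota, ")", call. = FALSE)
  }
  dplyr::arrange(dplyr::mutate(gene_table, hypervariable = hyper), .data$gene)
}

#' Select candidate genes containing at least one loss-of-function variant
#'
#' Genes flagged hypervariable (when the column is present) and the
#' unassigned sentinel bucket are dropped.
#'
#' @param gene_table Per-gene tibble, optionally with a `hypervariable`
#'   column from [exclude_hypervariable()].
#' @return Sorted character vector of gene symbols.
#' @export
select_lof_genes <- function(gene_table) {
  keep <- gene_table$lof_flag & !gene_table$unassigned
  if ("hypervariable" %in% names(gene_table)) {
    keep <- keep & !gene_table$hypervariable
  }
  sort(gene_table$gene[keep])
}

#' Family-deduplicated carrier counts per variant
#'
#' Counts, for each variant, the number of families with at least one
#' affected carrier; multiple affected carriers within one family contribute
#' a single occurrence. This is the case-side counting unit for the gene-set
#' burden test.
#'
#' @param variants Variant tibble with genotypes.
#' @param pedigree Pedigree tibble.
#' @return A tibble with columns `variant_id`, `gene`, `consequence`,
#'   `n_families` (families with >= 1 affected carrier).
#' @export
family_dedup_counts <- function(variants, pedigree) {
  fam_of <- stats::setNames(pedigree$family_id, pedigree$sample_id)
  affected_ids <- pedigree$sample_id[pedigree$affected %in% TRUE]
  tibble::tibble(
    variant_id = variants$variant_id,
    gene = variants$gene,
    consequence = variants$consequence,
    n_families = purrr::map_int(variants$genotypes, function(geno) {
      carriers <- names(geno)[!is.na(geno) & geno >= 1]
      dplyr::n_distinct(fam_of[intersect(carriers, affected_ids)])
    })
  )
}

#' Per-family segregation status of candidate variants
#'
#' A variant segregates in a family when every sequenced affected member
#' carries it; it fails when some sequenced affected member lacks it; a
#' family is uninformative when fewer than two members were sequenced or no
#' affected member was sequenced. Unaffected carriers do not break
#' segregation — the incomplete-penetrance convention under which an
#' unaffected sibling may carry the familial variant.
#'
#' @param variants Variant tibble with genotypes.
#' @param pedigree Pedigree tibble.
#' @param families Families to evaluate (default: all in the pedigree).
#' @return A tibble with one row per variant x family: `variant_id`, `gene`,
#'   `family_id`, `n_sequenced`, `affected_carriers`, `affected_total`,
#'   `unaffected_carriers`, `status` in
#'   `c("segregates", "fails", "uninformative")`.
#' @export
segregation_check <- function(variants, pedigree,
                              families = unique(pedigree$family_id)) {
  fam_members <- split(pedigree, pedigree$family_id)
  grid <- tidyr::expand_grid(
    idx = seq_len(nrow(variants)),
    family_id = families
  )
  rows <- purrr::pmap(grid, function(idx, family_id) {
    geno <- variants$genotypes[[idx]]
    mem <- fam_members[[family_id]]
    seq_ids <- intersect(mem$sample_id, names(geno)[!is.na(geno)])
    aff <- intersect(seq_ids, mem$sample_id[mem$affected %in% TRUE])
    unaff <- intersect(seq_ids, mem$sample_id[mem$affected %in% FALSE])
    aff_car <- sum(geno[aff] >= 1)
    status <- if (length(seq_ids) < 2 || length(aff) == 0) {
      "uninformative"
    } else if (aff_car == length(aff)) "segregates" else "fails"
    tibble::tibble(
      variant_id = variants$variant_id[idx],
      gene = variants$gene[idx],
      family_id = family_id,
      n_sequenced = length(seq_ids),
      affected_carriers = aff_car,
      affected_total = length(aff),
      unaffected_carriers = sum(geno[unaff] >= 1),
      status = status
    )
  })
  dplyr::bind_rows(rows)
}
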
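#' Candidate-gene selection from a per-gene summary
#'
#' Combines loss-of-function gene selection with hypervariable-gene
#' exclusion. By default the hypervariable top fraction is computed among
#' the LoF-containing genes (exclusion after selection); set
#' `hypervariable_first = TRUE` to exclude the top fraction of all genes
#' first and select LoF genes from the remainder.
#'
#' @param gene_table Per-gene tibble from [aggregate_by_gene()].
#' @param fraction Hypervariable fraction (default 0.01).
#' @param hypervariable_first Exclusion order (default `FALSE`).
#' @return Sorted character vector of candidate gene symbols.
#' @export
select_candidate_genes <- function(gene_table, fraction = 0.01,
                                   hypervariable_first = FALSE) {
  if (hypervariable_first) {
    select_lof_genes(exclude_hypervariable(gene_table, fraction))
  } else {
    lof <- dplyr::filter(gene_table, .data$lof_flag, !.data$unassigned)
    if (nrow(lof) == 0) return(character())
    select_lof_genes(exclude_hypervariable(lof, fraction))
  }
}

#' Run the full prioritisation and burden pipeline
#'
#' Executes filter -> gene aggregation -> candidate selection -> network
#' clustering -> term assignment -> gene-set burden test -> segregation
#' check -> (optional) cross-study carrier meta-analysis, writing one TSV
#' report per stage plus a machine-readable `summary.json` to `outdir`.
#' Re-running with identical inputs and options reproduces byte-identical
#' reports: the pipeline itself consumes no randomness.
#'
#' @param vcf,ped Paths to the annotated cohort VCF and PED pedigree.
#' @param network_file,gmt,control Paths to the interaction edge list, GMT
#'   gene sets, and control LoF count table.
#' @param outdir Output directory (created if needed).
#' @param study_records,panels,meta_gene Optional: path to a study carrier
#'   TSV, a reference-panel tibble or TSV path (`panel`, `gene`, `carriers`,
#'   `size`), and the gene to meta-analyse; all three enable the
#'   meta-analysis stage.
#' @param meta_probands,meta_exclusions Proband denominator and variant
#'   exclusion list for the meta-analysis stage.
#' @param max_control_af,missense_rule,keep_inframe,unknown_af_passes
#'   Filter options (see [filter_variants()]).
#' @param hypervariable_fraction,hypervariable_first Candidate-selection
#'   options (see [select_candidate_genes()]).
#' @param min_cluster_size,alpha,min_term_genes,max_term_genes Clustering
#'   and term-assignment thresholds.
#' @param burden_mode Contingency construction for the burden test.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(vcf, ped, network_file, gmt, control, outdir,
                         study_records = NULL, panels = NULL, meta_gene = NULL,
                         meta_probands = NULL, meta_exclusions = character(),
                         max_control_af = 0.05,
                         missense_rule = "both",
                         keep_inframe = TRUE,
                         unknown_af_passes = TRUE,
                         hypervariable_fraction = 0.01,
                         hypervariable_first = FALSE,
                         min_cluster_size = 5,
                         alpha = 0.05,
                         min_term_genes = 10,
                         max_term_genes = 200,
                         burden_mode = c("proportion_of_burden", "carrier")) {
  burden_mode <- match.arg(burden_mode)
  for (p in c(vcf, ped, network_file, gmt, control)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  variants <- read_cohort_vcf(vcf)
  pedigree <- read_pedigree(ped)
  net <- read_interaction_network(network_file)
  gene_sets <- read_gene_sets(gmt)
  control_counts <- read_control_counts(control)

  filtered <- filter_variants(variants, pedigree,
                              max_control_af = max_control_af,
                              missense_rule = missense_rule,
                              keep_inframe = keep_inframe,
                              unknown_af_passes = unknown_af_passes)
  flat <- dplyr::select(filtered, -"genotypes")
  readr::write_tsv(flat, file.path(outdir, "filtered_variants.tsv"))
  readr::write_tsv(filter_log(filtered), file.path(outdir, "filter_log.tsv"))

  gene_table <- aggregate_by_gene(filtered)
  candidates <- select_candidate_genes(gene_table, hypervariable_fraction,
                                       hypervariable_first)
  readr::write_tsv(
    dplyr::mutate(dplyr::select(gene_table, -"variant_ids"),
                  candidate = .data$gene %in% candidates),
    file.path(outdir, "gene_summary.tsv")
  )

  clusters <- if (length(candidates)) {
    find_clusters(net, candidates, min_size = min_cluster_size)
  } else {
    tibble::tibble(cluster_id = integer(), size = integer(), genes = list())
  }
  readr::write_tsv(
    dplyr::mutate(clusters, genes = purrr::map_chr(.data$genes, paste,
                                                   collapse = ",")),
    file.path(outdir, "clusters.tsv")
  )

  background <- sort(union(unique(unlist(gene_sets$genes)), candidates))
  assigned <- purrr::map2(clusters$cluster_id, clusters$genes, function(id, gs) {
    hit <- assign_term(gs, gene_sets, background, alpha = alpha,
                       min_genes = min_term_genes, max_genes = max_term_genes)
    if (nrow(hit)) dplyr::mutate(hit, cluster_id = id, .before = 1) else hit
  })
  assigned <- dplyr::bind_rows(assigned)
  if (nrow(assigned) == 0) {
    assigned <- tibble::tibble(cluster_id = integer(), term_id = character(),
                               term_size = integer(), overlap = integer(),
                               p_raw = numeric(), p_adj = numeric())
  }
  readr::write_tsv(assigned, file.path(outdir, "term_assignment.tsv"))

  burden <- purrr::map(assigned$term_id, function(tid) {
    tg <- gene_sets$genes[[match(tid, gene_sets$term_id)]]
    tidy(term_burden_test(tg, filtered, pedigree, control_counts,
                          mode = burden_mode, term_id = tid))
  })
  burden <- dplyr::bind_rows(burden)
  if (nrow(burden) == 0) {
    burden <- tibble::tibble(term_id = character(), mode = character(),
                             case_count = integer(), case_total = integer(),
                             control_count = integer(), control_total = integer(),
                             a = integer(), b = integer(), c = integer(),
                             d = integer(), p_value = numeric())
  }
  readr::write_tsv(burden, file.path(outdir, "burden.tsv"))

  cluster_genes <- unique(unlist(clusters$genes))
  seg_variants <- dplyr::filter(filtered, .data$gene %in% cluster_genes,
                                .data$consequence == "LOF")
  seg <- if (nrow(seg_variants)) {
    dplyr::filter(segregation_check(seg_variants, pedigree),
                  .data$affected_carriers > 0 | .data$unaffected_carriers > 0)
  } else {
    tibble::tibble(variant_id = character(), gene = character(),
                   family_id = character(), n_sequenced = integer(),
                   affected_carriers = integer(), affected_total = integer(),
                   unaffected_carriers = integer(), status = character())
  }
  readr::write_tsv(seg, file.path(outdir, "segregation.tsv"))

  meta <- NULL
  if (!is.null(study_records) && !is.null(panels) && !is.null(meta_gene)) {
    records <- read_study_records(study_records)
    panel_tbl <- if (is.character(panels)) {
      readr::read_tsv(panels, col_types = readr::cols(
        panel = readr::col_character(), gene = readr::col_character(),
        carriers = readr::col_integer(), size = readr::col_integer()
      ), comment = "#")
    } else panels
    meta <- tidy(carrier_meta_analysis(records, meta_gene, meta_probands,
                                       panel_tbl, meta_exclusions))
    readr::write_tsv(meta, file.path(outdir, "meta_analysis.tsv"))
  }

  summary <- list(
    counts = list(
      variants_input = nrow(variants),
      variants_filtered = nrow(filtered),
      genes = nrow(gene_table),
      candidate_genes = length(candidates),
      clusters = nrow(clusters),
      clustered_genes = length(cluster_genes)
    ),
    filter_log = filter_log(filtered),
    selected_terms = assigned$term_id,
    burden = burden,
    options = list(
      max_control_af = max_control_af, missense_rule = missense_rule,
      hypervariable_fraction = hypervariable_fraction,
      hypervariable_first = hypervariable_first,
      min_cluster_size = min_cluster_size, alpha = alpha,
      term_window = c(min_term_genes, max_term_genes),
      burden_mode = burden_mode
    )
  )
  if (!is.null(meta)) summary$meta <- meta
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(summary)
}
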
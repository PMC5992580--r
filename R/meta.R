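# Free-text consequence labels, as printed in published variant tables,
# normalised to the pipeline's consequence classes before carrier counting.
study_label_map <- c(
  "fs deletion"          = "LOF",
  "fs insertion"         = "LOF",
  "frameshift deletion"  = "LOF",
  "frameshift insertion" = "LOF",
  "frameshift"           = "LOF",
  "stop-site gain"       = "LOF",
  "stop site gain"       = "LOF",
  "stop gained"          = "LOF",
  "stop-site loss"       = "LOF",
  "start-site loss"      = "LOF",
  "start site loss"      = "LOF",
  "splice-site variant"  = "LOF",
  "splice-acceptor variant" = "LOF",
  "splice-donor variant" = "LOF",
  "in-frame deletion"    = "INFRAME_INDEL",
  "in-frame insertion"   = "INFRAME_INDEL",
  "missense"             = "MISSENSE",
  "missense variant"     = "MISSENSE"
)

#' Normalise free-text study consequence labels
#'
#' Published per-proband variant tables report consequences as prose labels
#' ("fs deletion", "Stop-site gain", ...). This maps them (case-insensitively)
#' onto the pipeline's classes; Sequence-Ontology terms are also accepted via
#' [classify_consequence()]. Unrecognised labels become `OTHER`.
#'
#' @param label Character vector of free-text consequence labels.
#' @return Character vector of consequence classes.
#' @export
normalise_study_consequence <- function(label) {
  key <- tolower(trimws(label))
  out <- unname(study_label_map[key])
  so <- is.na(out) & key %in% names(so_class_map)
  out[so] <- unname(so_class_map[key[so]])
  out[is.na(out)] <- "OTHER"
  out
}

#' Aggregate loss-of-function carriers for a gene across study records
#'
#' Counts distinct probands whose reported variant in `gene` is
#' loss-of-function, skipping rows with an exclusion flag and variants on
#' the exclusion list (for example a known benign polymorphic stop codon
#' removed from all datasets). A proband with several qualifying variants is
#' counted once; exact duplicate (study, patient, variant) rows are
#' collapsed with a warning.
#'
#' @param records Study-record tibble from [read_study_records()].
#' @param gene Gene symbol to aggregate.
#' @param total_probands Total probands screened across the contributing
#'   studies (the denominator, from the studies' reports).
#' @param exclusions Character vector of variant strings never counted.
#' @return A one-row tibble: `gene`, `carriers`, `n_probands`.
#' @export
aggregate_carriers <- function(records, gene, total_probands,
                               exclusions = character()) {
  rec <- dplyr::filter(records, .data$gene == !!gene)
  dup <- duplicated(rec[c("study", "patient_id", "variant")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (study, patient, variant) row(s) collapsed",
            call. = FALSE)
    rec <- rec[!dup, ]
  }
  qualifying <- rec |>
    dplyr::filter(
      is.na(.data$excluded) | !nzchar(.data$excluded),
      !(.data$variant %in% exclusions),
      normalise_study_consequence(.data$consequence) == "LOF"
    )
  carriers <- dplyr::n_distinct(qualifying$patient_id)
  if (total_probands < carriers) {
    stop("total_probands is smaller than the number of carriers", call. = FALSE)
  }
  tibble::tibble(gene = gene, carriers = carriers, n_probands = total_probands)
}

#' Carrier enrichment against a reference panel
#'
#' One-tailed Fisher exact test of
#' `[[carriers, n - carriers], [panel carriers, panel size - panel carriers]]`,
#' testing whether probands are enriched for carriers relative to the panel.
#'
#' @param carriers,n_probands Case carrier count and proband total.
#' @param panel_carriers,panel_size Reference-panel carrier count and size.
#' @return A single p-value.
#' @examples
#' carrier_enrichment(5, 329, 1, 503)
#' @export
carrier_enrichment <- function(carriers, n_probands, panel_carriers, panel_size) {
  stopifnot(carriers <= n_probands, panel_carriers <= panel_size)
  fisher_one_tailed_greater(carriers, n_probands - carriers,
                            panel_carriers, panel_size - panel_carriers)
}

#' Cross-study carrier meta-analysis for one gene
#'
#' Aggregates loss-of-function carriers from study records and tests
#' enrichment against each reference panel.
#'
#' @inheritParams aggregate_carriers
#' @param panels Tibble with columns `panel`, `gene`, `carriers`, `size`
#'   (reference-panel carrier counts for the same gene).
#' @return An object of class `"carrier_meta"` wrapping a per-panel tibble
#'   (`gene`, `carriers`, `n_probands`, `panel`, `panel_carriers`,
#'   `panel_size`, `p_value`); [tidy()] returns the tibble.
#' @export
carrier_meta_analysis <- function(records, gene, total_probands, panels,
                                  exclusions = character()) {
  agg <- aggregate_carriers(records, gene, total_probands, exclusions)
  pan <- dplyr::filter(panels, .data$gene == !!gene)
  if (nrow(pan) == 0) stop("no reference panel rows for gene ", gene, call. = FALSE)
  res <- dplyr::mutate(
    tibble::tibble(
      gene = gene, carriers = agg$carriers, n_probands = agg$n_probands,
      panel = pan$panel, panel_carriers = pan$carriers, panel_size = pan$size
    ),
    p_value = purrr::map2_dbl(.data$panel_carriers, .data$panel_size,
                              ~ carrier_enrichment(agg$carriers, agg$n_probands,
                                                   .x, .y))
  )
  structure(list(gene = gene, results = res), class = "carrier_meta")
}

#' @export
print.carrier_meta <- function(x, ...) {
  cat("Cross-study LoF carrier enrichment:", x$gene, "\n")
  print(x$results)
  invisible(x)
}

#' @rdname carrier_meta_analysis
#' @param x A `carrier_meta` object.
#' @param ... Unused.
#' @method tidy carrier_meta
#' @export
tidy.carrier_meta <- function(x, ...) x$results

#' @rdname carrier_meta_analysis
#' @method glance carrier_meta
#' @export
glance.carrier_meta <- function(x, ...) {
  tibble::tibble(
    gene = x$gene,
    carriers = x$results$carriers[1],
    n_probands = x$results$n_probands[1],
    n_panels = nrow(x$results),
    min_p = min(x$results$p_value)
  )
}
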
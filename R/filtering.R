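#' Flag protein-affecting variants
#'
#' A variant is protein-affecting when it is loss-of-function, an in-frame
#' indel (when `keep_inframe`), or a missense variant that satisfies the
#' prediction rule: SIFT "deleterious" and/or PolyPhen damaging, depending on
#' `missense_rule`. PolyPhen "possibly_damaging" counts as damaging by
#' default. Missense variants with missing predictions fail the rule
#' (conservative default).
#'
#' @param variants Variant tibble with `consequence`, `sift`, `polyphen`.
#' @param missense_rule `"both"` (default; both predictors must concur) or
#'   `"either"`.
#' @param keep_inframe Keep in-frame indels unconditionally (default `TRUE`).
#' @param possibly_damaging_counts Treat PolyPhen `"possibly_damaging"` as
#'   damaging (default `TRUE`).
#' @return Logical vector, one element per variant row.
#' @export
is_protein_affecting <- function(variants, missense_rule = c("both", "either"),
                                 keep_inframe = TRUE,
                                 possibly_damaging_counts = TRUE) {
  missense_rule <- match.arg(missense_rule)
  damaging_levels <- if (possibly_damaging_counts) {
    c("probably_damaging", "possibly_damaging")
  } else "probably_damaging"
  sift_hit <- variants$sift == "deleterious"
  poly_hit <- variants$polyphen %in% damaging_levels
  missense_ok <- if (missense_rule == "both") sift_hit & poly_hit else sift_hit | poly_hit
  dplyr::case_when(
    variants$consequence == "LOF" ~ TRUE,
    variants$consequence == "INFRAME_INDEL" ~ keep_inframe,
    variants$consequence == "MISSENSE" ~ missense_ok,
    TRUE ~ FALSE
  )
}

#' Filter a cohort's variants to rare protein-affecting candidates
#'
#' Applies the three candidate-selection rules in order: (i) rarity — control
#' allele frequency below `max_control_af` (variants absent from the
#' reference panel pass by default, absence implying rarity); (ii)
#' protein-affecting consequence (see [is_protein_affecting()]); (iii)
#' carried by at least one affected cohort member. Variants whose genotypes
#' are all missing are dropped first, with a warning. Input row order is
#' preserved; per-rule removal counts are attached as the `"filter_log"`
#' attribute (see [filter_log()]).
#'
#' @param variants Variant tibble from [read_cohort_vcf()] or
#'   [simulate_cohort()].
#' @param pedigree Pedigree tibble; `affected` marks the case samples.
#' @param max_control_af Rarity threshold on the control allele frequency
#'   (default 0.05, exclusive).
#' @param unknown_af_passes Do variants with missing control AF pass the
#'   rarity rule (default `TRUE`)?
#' @inheritParams is_protein_affecting
#' @return The retained rows, with `affected_carriers` and
#'   `unaffected_carriers` columns appended and a `filter_log` attribute.
#' @export
filter_variants <- function(variants, pedigree,
                            max_control_af = 0.05,
                            missense_rule = c("both", "either"),
                            keep_inframe = TRUE,
                            unknown_af_passes = TRUE,
                            possibly_damaging_counts = TRUE) {
  stopifnot(max_control_af > 0, max_control_af <= 1)
  missense_rule <- match.arg(missense_rule)

  affected_ids <- pedigree$sample_id[pedigree$affected %in% TRUE]
  unaffected_ids <- pedigree$sample_id[pedigree$affected %in% FALSE]
  if (length(affected_ids) == 0) {
    stop("pedigree contains no affected samples", call. = FALSE)
  }
  unknown <- setdiff(names(variants$genotypes[[1]]), pedigree$sample_id)
  if (length(unknown)) {
    stop("VCF samples absent from pedigree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  carriers <- function(geno, ids) sum(geno[ids] >= 1, na.rm = TRUE)
  variants <- dplyr::mutate(
    variants,
    affected_carriers = purrr::map_int(.data$genotypes, carriers, ids = affected_ids),
    unaffected_carriers = purrr::map_int(.data$genotypes, carriers, ids = unaffected_ids)
  )

  log <- list()
  n0 <- nrow(variants)

  all_missing <- purrr::map_lgl(variants$genotypes, ~ all(is.na(.x)))
  if (any(all_missing)) {
    warning(sum(all_missing), " variant(s) dropped: all genotypes missing",
            call. = FALSE)
  }
  variants <- variants[!all_missing, ]
  log$all_genotypes_missing <- sum(all_missing)

  rare <- dplyr::if_else(is.na(variants$control_af), unknown_af_passes,
                         variants$control_af < max_control_af)
  log$common_in_controls <- sum(!rare)
  variants <- variants[rare, ]

  affecting <- is_protein_affecting(variants, missense_rule, keep_inframe,
                                    possibly_damaging_counts)
  log$not_protein_affecting <- sum(!affecting)
  variants <- variants[affecting, ]

  carried <- variants$affected_carriers >= 1
  log$no_affected_carrier <- sum(!carried)
  variants <- variants[carried, ]

  log_tbl <- tibble::tibble(
    rule = names(log),
    removed = as.integer(unlist(log))
  )
  log_tbl$remaining <- n0 - cumsum(log_tbl$removed)
  attr(variants, "filter_log") <- log_tbl
  variants
}

#' Per-rule removal counts from the last filtering pass
#'
#' @param filtered A tibble returned by [filter_variants()].
#' @return A tibble with columns `rule`, `removed`, `remaining`.
#' @export
filter_log <- function(filtered) {
  log <- attr(filtered, "filter_log")
  if (is.null(log)) stop("no filter_log attribute; was this filtered?", call. = FALSE)
  log
}
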
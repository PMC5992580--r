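#' Gene-set loss-of-function burden test against a control cohort
#'
#' Aggregates family-deduplicated loss-of-function occurrences over every
#' filtered gene annotated to the term (regardless of interaction
#' clustering) and compares them with aggregated control-panel counts by a
#' one-tailed Fisher exact test (cases enriched).
#'
#' Two contingency-table constructions are offered. The default,
#' `"proportion_of_burden"`, uses each cohort's total filtered LoF count as
#' the denominator source — `[in-term, out-of-term] x [cases, controls]` —
#' which is robust to overall depth/annotation differences against an
#' externally produced control set. `"carrier"` instead uses chromosomes as
#' denominators: `[count, 2 x cohort size - count]`, where the case cohort
#' size is the number of families (the deduplication unit) and the control
#' cohort size comes from the control table.
#'
#' @param term_genes Symbols annotated to the term.
#' @param case_variants Pipeline-filtered variant tibble (see
#'   [filter_variants()]).
#' @param pedigree Pedigree tibble.
#' @param control_counts Control tibble from [read_control_counts()]; must be
#'   filtered comparably to the cases.
#' @param mode Contingency construction (see Details).
#' @param term_id Optional label carried into the result.
#' @return An object of class `"lof_burden"`: a list with the term id, mode,
#'   in-term and total counts for both cohorts, the 2x2 cells `a`-`d`, and
#'   the one-tailed p. [tidy()] and [glance()] methods return tibbles.
#' @export
term_burden_test <- function(term_genes, case_variants, pedigree,
                             control_counts,
                             mode = c("proportion_of_burden", "carrier"),
                             term_id = NA_character_) {
  mode <- match.arg(mode)
  dedup <- family_dedup_counts(case_variants, pedigree)
  lof <- dplyr::filter(dedup, .data$consequence == "LOF")
  case_total <- sum(lof$n_families)
  case_in <- sum(lof$n_families[lof$gene %in% term_genes])
  control_total <- sum(control_counts$allele_count)
  control_in <- sum(control_counts$allele_count[control_counts$gene %in% term_genes])
  if (case_total == 0 || control_total == 0) {
    stop("zero total loss-of-function counts in ",
         if (case_total == 0) "case" else "control",
         " cohort; burden test undefined", call. = FALSE)
  }
  if (mode == "proportion_of_burden") {
    cells <- c(a = case_in, b = case_total - case_in,
               c = control_in, d = control_total - control_in)
  } else {
    n_fam <- dplyr::n_distinct(pedigree$family_id)
    n_ctrl <- control_counts$cohort_size[1]
    if (case_in > 2 * n_fam || control_in > 2 * n_ctrl) {
      stop("carrier mode undefined: in-term count exceeds chromosome count",
           call. = FALSE)
    }
    cells <- c(a = case_in, b = 2 * n_fam - case_in,
               c = control_in, d = 2 * n_ctrl - control_in)
  }
  structure(
    list(
      term_id = term_id, mode = mode,
      case_count = case_in, case_total = case_total,
      control_count = control_in, control_total = control_total,
      table = cells,
      p_value = fisher_one_tailed_greater(cells["a"], cells["b"],
                                          cells["c"], cells["d"])
    ),
    class = "lof_burden"
  )
}

#' @export
print.lof_burden <- function(x, ...) {
  cat("Gene-set LoF burden test (one-tailed Fisher, mode:", x$mode, ")\n")
  cat(sprintf("  term: %s\n", x$term_id))
  cat(sprintf("  cases:    %d in-term of %d total (family-deduplicated)\n",
              x$case_count, x$case_total))
  cat(sprintf("  controls: %d in-term of %d total alleles\n",
              x$control_count, x$control_total))
  cat(sprintf("  2x2 [a b; c d] = [%d %d; %d %d]\n",
              x$table["a"], x$table["b"], x$table["c"], x$table["d"]))
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname term_burden_test
#' @param x An `lof_burden` object.
#' @param ... Unused.
#' @method tidy lof_burden
#' @export
tidy.lof_burden <- function(x, ...) {
  tibble::tibble(
    term_id = x$term_id, mode = x$mode,
    case_count = x$case_count, case_total = x$case_total,
    control_count = x$control_count, control_total = x$control_total,
    a = unname(x$table["a"]), b = unname(x$table["b"]),
    c = unname(x$table["c"]), d = unname(x$table["d"]),
    p_value = x$p_value
  )
}

#' @rdname term_burden_test
#' @method glance lof_burden
#' @export
glance.lof_burden <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    case_rate = x$case_count / x$case_total,
    control_rate = x$control_count / x$control_total,
    p_value = x$p_value
  )
}
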
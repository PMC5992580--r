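#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a gene-set burden result
#'
#' Side-by-side in-term loss-of-function proportions for cases and controls,
#' annotated with the one-tailed Fisher p.
#'
#' @param object An `lof_burden` object from [term_burden_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lof_burden
#' @export
autoplot.lof_burden <- function(object, ...) {
  df <- tibble::tibble(
    cohort = factor(c("cases", "controls"), levels = c("cases", "controls")),
    in_term = c(object$case_count, object$control_count),
    total = c(object$case_total, object$control_total)
  )
  df$proportion <- df$in_term / df$total
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cohort, y = .data$proportion,
                                   fill = .data$cohort)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d / %d", .data$in_term,
                                                    .data$total)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(
      title = sprintf("LoF burden in %s", object$term_id),
      subtitle = sprintf("one-tailed Fisher p = %.3g (%s mode)",
                         object$p_value, object$mode),
      x = NULL, y = "in-term share of filtered LoF burden"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cross-study carrier meta-analysis
#'
#' Carrier frequencies in the proband pool and each reference panel with the
#' per-panel one-tailed enrichment p.
#'
#' @param object A `carrier_meta` object from [carrier_meta_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot carrier_meta
#' @export
autoplot.carrier_meta <- function(object, ...) {
  res <- object$results
  df <- dplyr::bind_rows(
    tibble::tibble(group = "probands",
                   freq = res$carriers[1] / res$n_probands[1],
                   label = sprintf("%d / %d", res$carriers[1], res$n_probands[1]),
                   p = NA_real_),
    tibble::tibble(group = res$panel,
                   freq = res$panel_carriers / res$panel_size,
                   label = sprintf("%d / %d", res$panel_carriers, res$panel_size),
                   p = res$p_value)
  )
  df$group <- factor(df$group, levels = df$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$freq)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4, size = 3) +
    ggplot2::labs(
      title = sprintf("%s loss-of-function carrier frequency", object$gene),
      subtitle = paste(
        stats::na.omit(sprintf("%s: p = %.3g", df$group, df$p)), collapse = "; "),
      x = NULL, y = "carrier frequency"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-rule filtering attrition
#'
#' Remaining variant counts after each filter rule, from the log attached by
#' [filter_variants()].
#'
#' @param filtered A tibble returned by [filter_variants()].
#' @return A ggplot.
#' @export
plot_filter_log <- function(filtered) {
  log <- filter_log(filtered)
  log$rule <- factor(log$rule, levels = log$rule)
  ggplot2::ggplot(log, ggplot2::aes(x = .data$rule, y = .data$remaining)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("-%d", .data$removed)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "variants remaining",
                  title = "Variant-filter attrition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
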
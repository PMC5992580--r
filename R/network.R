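#' Clusters of physically interacting candidate genes
#'
#' Induces the subgraph of the interaction network on the candidate genes and
#' returns its connected components of at least `min_size` members. A cluster
#' is a set of five or more physically interacting genes by default.
#' Ordering is deterministic: by size descending, then by the
#' lexicographically first member.
#'
#' @param network Edge tibble (`from`, `to`) from [read_interaction_network()].
#' @param candidates Character vector of candidate gene symbols.
#' @param min_size Minimum cluster size (default 5).
#' @return A tibble with columns `cluster_id`, `size`, and a `genes`
#'   list-column (members sorted); zero rows when no component qualifies.
#' @export
find_clusters <- function(network, candidates, min_size = 5) {
  if (length(candidates) == 0) stop("no candidate genes supplied", call. = FALSE)
  candidates <- unique(candidates)
  edges <- dplyr::filter(network, .data$from %in% candidates,
                         .data$to %in% candidates)
  empty <- tibble::tibble(cluster_id = integer(), size = integer(),
                          genes = list())
  if (nrow(edges) == 0) return(empty)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = candidates)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- purrr::map(members, sort)
  members <- members[lengths(members) >= min_size]
  if (length(members) == 0) return(empty)
  ord <- order(-lengths(members), purrr::map_chr(members, 1))
  tibble::tibble(
    cluster_id = seq_along(ord),
    size = unname(lengths(members)[ord]),
    genes = unname(members[ord])
  )
}

#' Hypergeometric over-representation of an annotation term in a cluster
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a gene cluster and a term's annotated genes, drawing
#' `|cluster|` genes from the background universe.
#'
#' @param cluster_genes Cluster member symbols (must all be in `background`).
#' @param term_genes Symbols annotated to the term.
#' @param background Background gene universe.
#' @return A single p-value.
#' @export
over_representation_test <- function(cluster_genes, term_genes, background) {
  cluster_genes <- unique(cluster_genes)
  background <- unique(background)
  if (!all(cluster_genes %in% background)) {
    stop("cluster genes must be a subset of the background universe",
         call. = FALSE)
  }
  term_in_bg <- intersect(unique(term_genes), background)
  k <- length(intersect(cluster_genes, term_in_bg))
  hypergeom_sf_ge(k, N = length(background), K = length(term_in_bg),
                  n = length(cluster_genes))
}

#' Over-representation report for one cluster across all terms
#'
#' Raw hypergeometric p per term, Bonferroni-adjusted across `n_tests` terms
#' (default: every term supplied, the conservative reading of tools that
#' correct over the whole annotation), with the size-window eligibility used
#' by [assign_term()].
#'
#' @param cluster_genes Cluster member symbols.
#' @param gene_sets Gene-set tibble from [read_gene_sets()].
#' @param background Background gene universe.
#' @param min_genes,max_genes Annotated-size window for eligibility
#'   (defaults 10 and 200).
#' @param n_tests Bonferroni denominator (default `nrow(gene_sets)`).
#' @return A tibble: `term_id`, `term_size`, `overlap`, `p_raw`, `p_adj`,
#'   `in_window`, sorted by `p_adj` then term size then id.
#' @export
test_cluster_terms <- function(cluster_genes, gene_sets, background,
                               min_genes = 10, max_genes = 200,
                               n_tests = nrow(gene_sets)) {
  if (nrow(gene_sets) == 0) stop("no gene sets supplied", call. = FALSE)
  p_raw <- purrr::map_dbl(gene_sets$genes, over_representation_test,
                          cluster_genes = cluster_genes,
                          background = background)
  tibble::tibble(
    term_id = gene_sets$term_id,
    term_size = gene_sets$term_size,
    overlap = purrr::map_int(gene_sets$genes,
                             ~ length(intersect(cluster_genes, .x))),
    p_raw = p_raw,
    p_adj = bonferroni_adjust(p_raw, m = n_tests),
    in_window = gene_sets$term_size >= min_genes & gene_sets$term_size <= max_genes
  ) |>
    dplyr::arrange(.data$p_adj, .data$term_size, .data$term_id)
}

#' Assign the best-supported annotation term to a gene cluster
#'
#' Among terms significant after Bonferroni correction (`p_adj < alpha`) and
#' annotated to between `min_genes` and `max_genes` genes, returns the term
#' with the smallest adjusted p (ties broken by smaller term, then
#' lexicographic id). Zero rows when no term qualifies.
#'
#' @inheritParams test_cluster_terms
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return A one-row tibble (`term_id`, `term_size`, `overlap`, `p_raw`,
#'   `p_adj`) or a zero-row tibble.
#' @export
assign_term <- function(cluster_genes, gene_sets, background, alpha = 0.05,
                        min_genes = 10, max_genes = 200,
                        n_tests = nrow(gene_sets)) {
  report <- test_cluster_terms(cluster_genes, gene_sets, background,
                               min_genes, max_genes, n_tests)
  hits <- dplyr::filter(report, .data$in_window, .data$p_adj < alpha)
  dplyr::select(utils::head(hits, 1), -"in_window")
}
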
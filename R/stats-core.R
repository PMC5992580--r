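#' Exact hypergeometric probability mass
#'
#' Probability of drawing exactly `k` marked items when `n` items are drawn
#' without replacement from a population of `N` items of which `K` are marked.
#' Computed in log space with [lchoose()] so that large cohorts (for example a
#' 27,000-individual reference panel) do not overflow; out-of-support `k`
#' returns 0 rather than erroring.
#'
#' @param k Number of marked items drawn (vectorised).
#' @param N Population size.
#' @param K Number of marked items in the population.
#' @param n Number of draws.
#' @return Numeric vector of probabilities, same length as `k`.
#' @examples
#' hypergeom_pmf(2, N = 10, K = 3, n = 5) # 105/252
#' @export
hypergeom_pmf <- function(k, N, K, n) {
  check_hyper_params(N, K, n)
  k <- as.numeric(k)
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  out <- numeric(length(k))
  ok <- !is.na(k) & k >= lo & k <= hi & k == floor(k)
  out[ok] <- exp(lchoose(K, k[ok]) + lchoose(N - K, n - k[ok]) - lchoose(N, n))
  out[is.na(k)] <- NA_real_
  out
}

#' Exact hypergeometric upper-tail probability P(X >= k)
#'
#' The one-tailed enrichment tail underlying the Fisher exact test: summed
#' pointwise in log space over the support `k ... min(n, K)`. Never returns a
#' hard zero; the smallest tails come back as the log-space sum evaluates them.
#'
#' @inheritParams hypergeom_pmf
#' @return Numeric vector of tail probabilities in (0, 1].
#' @examples
#' hypergeom_sf_ge(2, N = 10, K = 3, n = 5) # exactly 0.5
#' @export
hypergeom_sf_ge <- function(k, N, K, n) {
  check_hyper_params(N, K, n)
  lo <- max(0, n + K - N)
  hi <- min(n, K)
  vapply(as.numeric(k), function(ki) {
    if (is.na(ki)) return(NA_real_)
    if (ki <= lo) return(1)
    if (ki > hi) return(0)
    js <- seq(ceiling(ki), hi)
    lp <- lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)
    m <- max(lp)
    min(1, exp(m + log(sum(exp(lp - m)))))
  }, numeric(1))
}

check_hyper_params <- function(N, K, n) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1)
  if (is.na(N) || is.na(K) || is.na(n) ||
      K < 0 || n < 0 || K > N || n > N) {
    stop("invalid hypergeometric parameters: need 0 <= K <= N and 0 <= n <= N",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' One-tailed Fisher exact test for enrichment in cases
#'
#' Tests whether the exposure in cell `a` is enriched in cases, i.e. the upper
#' hypergeometric tail P(X >= a) with margins fixed. The table is oriented as
#'
#' \preformatted{          exposed  unexposed
#'   cases       a         b
#'   controls    c         d}
#'
#' Direction is fixed ("cases enriched for exposure"): callers orient the
#' table. All cells must be non-negative integers with at least one positive.
#'
#' @param a,b,c,d Cell counts (see layout above).
#' @return A single p-value in (0, 1].
#' @examples
#' fisher_one_tailed_greater(5, 324, 1, 502)
#' @export
fisher_one_tailed_greater <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    stop("contingency cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) {
    stop("empty contingency table", call. = FALSE)
  }
  hypergeom_sf_ge(a, N = a + b + c + d, K = a + c, n = a + b)
}

#' Bonferroni multiple-testing adjustment
#'
#' `min(1, p * m)` for each p, with `m` defaulting to the number of tests
#' supplied. `m` is exposed because over-representation tools differ on
#' whether the correction counts every annotation term or only terms with
#' nonzero overlap; the default counts everything supplied.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Number of tests; defaults to `length(p)`.
#' @return Adjusted p-values, order preserved.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (length(p) == 0) stop("empty p-value list", call. = FALSE)
  if (m == length(p)) {
    stats::p.adjust(p, method = "bonferroni")
  } else {
    pmin(1, p * m)
  }
}
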
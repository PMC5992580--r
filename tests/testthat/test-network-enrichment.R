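edge_tbl <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(from = m[, 1], to = m[, 2])
}

test_that("clusters are connected components of the induced candidate subgraph", {
  # a planted 8-clique among candidates comes back as one cluster of 8
  clique <- sprintf("c%d", 1:8)
  edges <- t(utils::combn(clique, 2))
  net <- tibble::tibble(from = edges[, 1], to = edges[, 2])
  cl <- find_clusters(net, c(clique, "lone1", "lone2"))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$genes[[1]], sort(clique))

  # pairs never reach the minimum size
  net2 <- edge_tbl("a", "b", "c", "d", "e", "f")
  expect_equal(nrow(find_clusters(net2, letters[1:6])), 0)

  # two qualifying components are ordered by size
  chain <- function(v) edge_tbl(rbind(v[-length(v)], v[-1]))
  big <- sprintf("b%02d", 1:10); small <- sprintf("s%d", 1:5)
  net3 <- dplyr::bind_rows(chain(big), chain(small))
  cl3 <- find_clusters(net3, c(big, small))
  expect_equal(cl3$size, c(10L, 5L))
  expect_equal(cl3$genes[[2]], sort(small))
})

test_that("clusters are disjoint and internally reachable (brute-force oracle)", {
  set.seed(19)
  genes <- sprintf("g%02d", 1:50)
  for (rep in 1:5) {
    pairs <- t(utils::combn(genes, 2))
    pick <- pairs[stats::runif(nrow(pairs)) < 0.04, , drop = FALSE]
    net <- tibble::tibble(from = pick[, 1], to = pick[, 2])
    cand <- sample(genes, 30)
    cl <- find_clusters(net, cand, min_size = 3)
    all_members <- unlist(cl$genes)
    expect_equal(anyDuplicated(all_members), 0)
    # reachability oracle: repeated neighbour expansion over candidate edges
    adj <- dplyr::filter(net, from %in% cand, to %in% cand)
    reach <- function(seed) {
      comp <- seed
      repeat {
        nb <- c(adj$to[adj$from %in% comp], adj$from[adj$to %in% comp])
        new <- setdiff(nb, comp)
        if (length(new) == 0) return(sort(comp))
        comp <- c(comp, new)
      }
    }
    for (members in cl$genes) {
      expect_equal(reach(members[1]), members)
    }
  }
})

test_that("over-representation equals the hypergeometric tail and the Fisher table", {
  bg <- sprintf("g%02d", 1:20)
  cluster <- bg[1:5]
  term <- bg[c(1, 2, 10, 11)]        # overlap k = 2, K = 4, n = 5, N = 20
  p <- over_representation_test(cluster, term, bg)
  expect_equal(p, 3856 / 15504, tolerance = 1e-12)
  # cross-module identity with the 2x2 formulation
  expect_equal(p, fisher_one_tailed_greater(2, 3, 2, 13))
  # zero overlap spans the whole upper tail
  expect_equal(over_representation_test(bg[1:5], bg[11:14], bg), 1)
  # full overlap with a term of exactly the cluster size is the minimal tail
  p_full <- over_representation_test(bg[1:5], bg[1:5], bg)
  p_partial <- over_representation_test(bg[1:5], bg[c(1:4, 10)], bg)
  expect_lt(p_full, p_partial)
  expect_error(over_representation_test(c(cluster, "zz"), term, bg), "subset")
})

test_that("term assignment applies the size window, Bonferroni and tie-breaks", {
  bg <- sprintf("g%04d", 1:2000)
  cluster <- bg[1:8]
  sets <- tibble::tibble(
    term_id = c("INWINDOW", "HUGE", "DECOY"),
    # HUGE covers the whole cluster (most significant raw hit) but has 300
    # genes; INWINDOW covers 4 of 8 with 20 genes
    genes = list(bg[c(1:4, 1001:1016)], bg[1:300], bg[1501:1540]),
    term_size = c(20L, 300L, 40L)
  )
  report <- test_cluster_terms(cluster, sets, bg)
  expect_lt(report$p_raw[report$term_id == "HUGE"],
            report$p_raw[report$term_id == "INWINDOW"])
  expect_false(report$in_window[report$term_id == "HUGE"])
  expect_lt(report$p_adj[report$term_id == "HUGE"], 0.05)
  # the eligible-but-less-significant term wins the assignment
  hit <- assign_term(cluster, sets, bg)
  expect_equal(hit$term_id, "INWINDOW")
  # nothing significant -> empty assignment
  none <- assign_term(cluster, sets[3, ], bg)
  expect_equal(nrow(none), 0)
  # Bonferroni m: with a larger denominator the adjusted p grows
  r2 <- test_cluster_terms(cluster, sets, bg, n_tests = 1000)
  expect_true(all(r2$p_adj >= report$p_adj[match(r2$term_id, report$term_id)]))
})

test_that("burden test builds both contingency modes and delegates to Fisher", {
  ped <- make_ped(affected = list(F1 = "a1", F2 = "b1"))
  v <- make_variants(
    make_variant("T1", "stop_gained", c(a1 = 1, b1 = 0), pos = 1),
    make_variant("T1", "frameshift_variant", c(a1 = 0, b1 = 1), pos = 2),
    make_variant("B1", "stop_gained", c(a1 = 1, b1 = 1), pos = 3),
    make_variant("B2", "missense_variant", c(a1 = 1, b1 = 1), pos = 4,
                 sift = "deleterious", polyphen = "probably_damaging")
  )
  ctrl <- tibble::tibble(gene = c("T1", "B1"),
                         allele_count = c(2L, 6L), cohort_size = 50L)
  b <- term_burden_test("T1", v, ped, ctrl, term_id = "T1")
  # cases: T1 dedup = 1 + 1 families; totals exclude the missense variant
  expect_equal(b$case_count, 2)
  expect_equal(b$case_total, 4)
  expect_equal(b$control_count, 2)
  expect_equal(b$control_total, 8)
  expect_equal(unname(b$table), c(2, 2, 2, 6))
  expect_equal(b$p_value, fisher_one_tailed_greater(2, 2, 2, 6))

  bc <- term_burden_test("T1", v, ped, ctrl, mode = "carrier")
  expect_equal(unname(bc$table), c(2, 2 * 2 - 2, 2, 2 * 50 - 2))

  td <- tidy(b)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p_value, b$p_value)
  expect_equal(glance(b)$case_rate, 0.5)
})

test_that("burden test is calibrated on matched proportions and errors on empty cohorts", {
  ped <- make_ped(affected = list(F1 = "a1"))
  v <- make_variants(
    make_variant("T1", "stop_gained", c(a1 = 1), pos = 1),
    make_variant("B1", "stop_gained", c(a1 = 1), pos = 2)
  )
  # identical in-term shares in both cohorts cannot signal enrichment
  ctrl_same <- tibble::tibble(gene = c("T1", "B1"),
                              allele_count = c(50L, 50L), cohort_size = 100L)
  expect_gte(term_burden_test("T1", v, ped, ctrl_same)$p_value, 0.5)
  ctrl_zero <- tibble::tibble(gene = "T1", allele_count = 0L, cohort_size = 10L)
  expect_error(term_burden_test("T1", v, ped, ctrl_zero), "zero total")
  v_mis <- make_variant("T1", "missense_variant", c(a1 = 1),
                        sift = "deleterious", polyphen = "probably_damaging")
  expect_error(term_burden_test("T1", v_mis, ped, ctrl_same), "zero total")
})
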
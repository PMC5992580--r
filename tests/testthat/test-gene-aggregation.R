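test_that("variants partition into genes with conserved totals", {
  v <- make_variants(
    make_variant("PALB2", "frameshift_variant", c(s1 = 1), pos = 1),
    make_variant("PALB2", "missense_variant", c(s1 = 1), pos = 2,
                 sift = "deleterious", polyphen = "probably_damaging"),
    make_variant("PALB2", "stop_gained", c(s1 = 1), pos = 3),
    make_variant("MSH2", "start_lost", c(s1 = 1), pos = 4)
  )
  tbl <- aggregate_by_gene(v)
  expect_equal(tbl$gene, c("MSH2", "PALB2"))
  expect_equal(tbl$n_variants, c(1L, 3L))
  expect_equal(tbl$n_lof, c(1L, 2L))
  expect_true(all(tbl$lof_flag))
  expect_equal(sum(tbl$n_variants), nrow(v))
  expect_equal(nrow(aggregate_by_gene(v[0, ])), 0)
})

test_that("a hand-tallied 10-variant fixture collapses to the expected counts", {
  genes <- c("A", "A", "A", "A", "B", "B", "B", "C", "C", "D")
  cons <- c("stop_gained", "missense_variant", "missense_variant", "synonymous_variant",
            "frameshift_variant", "frameshift_variant", "missense_variant",
            "missense_variant", "missense_variant", "inframe_deletion")
  v <- dplyr::bind_rows(purrr::map2(
    genes, seq_along(genes),
    ~ make_variant(.x, cons[.y], c(s1 = 1), pos = .y * 10)
  ))
  tbl <- aggregate_by_gene(v)
  expect_equal(tbl$n_variants, c(A = 4L, B = 3L, C = 2L, D = 1L),
               ignore_attr = TRUE)
  expect_equal(tbl$n_lof, c(1L, 2L, 0L, 0L))
  expect_equal(select_lof_genes(tbl), c("A", "B"))
})

test_that("unassigned gene symbols go to a sentinel bucket excluded downstream", {
  v <- make_variants(
    make_variant(NA_character_, "stop_gained", c(s1 = 1), pos = 1),
    make_variant("X", "stop_gained", c(s1 = 1), pos = 2)
  )
  tbl <- aggregate_by_gene(v)
  expect_true(".unassigned" %in% tbl$gene)
  expect_equal(select_lof_genes(tbl), "X")
})

test_that("hypervariable exclusion takes the top fraction with tie-group expansion", {
  tbl <- tibble::tibble(
    gene = sprintf("g%03d", 1:200),
    n_variants = c(30L, 25L, rep(2L, 198)),
    n_lof = 1L, lof_flag = TRUE,
    variability_count = c(30L, 25L, rep(2L, 198)),
    unassigned = FALSE, variant_ids = list(character())
  )
  out <- exclude_hypervariable(tbl)
  expect_equal(sort(out$gene[out$hypervariable]), c("g001", "g002"))

  # counts {g1:9, g2:9, g3:2, ..., g100:1}: quota 1, tie at the cut -> both
  tbl2 <- tibble::tibble(
    gene = sprintf("g%03d", 1:100),
    n_variants = c(9L, 9L, 2L, rep(1L, 97)),
    n_lof = 1L, lof_flag = TRUE,
    variability_count = c(9L, 9L, 2L, rep(1L, 97)),
    unassigned = FALSE, variant_ids = list(character())
  )
  expect_warning(out2 <- exclude_hypervariable(tbl2), "tie")
  expect_equal(sort(out2$gene[out2$hypervariable]), c("g001", "g002"))

  # all equal: the whole tie group goes, with a warning
  tbl3 <- dplyr::mutate(tbl2, variability_count = 3L)
  expect_warning(out3 <- exclude_hypervariable(tbl3), "tie")
  expect_true(all(out3$hypervariable))

  expect_error(exclude_hypervariable(tbl2, fraction = 1), "fraction")
  expect_error(exclude_hypervariable(tbl2[0, ]), "empty")
})

test_that("exclusion removes at least the quota and only counts at or above the cut", {
  set.seed(3)
  for (i in 1:10) {
    g <- sample(20:400, 1)
    tbl <- tibble::tibble(
      gene = sprintf("g%04d", seq_len(g)),
      n_variants = 1L, n_lof = 1L, lof_flag = TRUE,
      variability_count = sample(1:15, g, replace = TRUE),
      unassigned = FALSE, variant_ids = list(character())
    )
    out <- suppressWarnings(exclude_hypervariable(tbl, 0.05))
    quota <- ceiling(0.05 * g)
    excluded <- out$variability_count[out$hypervariable]
    kept <- out$variability_count[!out$hypervariable]
    expect_gte(length(excluded), quota)
    expect_true(all(excluded >= max(kept)))
  }
})

test_that("family deduplication counts each affected family once", {
  ped <- make_ped(
    affected = list(FAM1 = c("a1", "a2", "a3"), FAM2 = "b1"),
    unaffected = list(FAM1 = "u1", FAM2 = "u2")
  )
  v <- make_variants(
    make_variant("G1", "stop_gained", c(a1 = 1, a2 = 1, a3 = 1, u1 = 0, b1 = 0, u2 = 0), pos = 1),
    make_variant("G2", "stop_gained", c(a1 = 1, a2 = 0, a3 = 0, u1 = 0, b1 = 2, u2 = 0), pos = 2),
    make_variant("G3", "stop_gained", c(a1 = 0, a2 = 0, a3 = 0, u1 = 1, b1 = 0, u2 = 1), pos = 3)
  )
  counts <- family_dedup_counts(v, ped)
  expect_equal(counts$n_families, c(1L, 2L, 0L))
  # never exceeds the per-sample carrier tally
  per_sample <- purrr::map_int(v$genotypes, ~ sum(.x >= 1, na.rm = TRUE))
  expect_true(all(counts$n_families <= per_sample))
})

test_that("segregation follows the incomplete-penetrance convention", {
  ped <- make_ped(
    affected = list(FAM11 = c("p1", "p2", "p3"), FAM4 = "q1", FAM9 = "r1"),
    unaffected = list(FAM11 = "p4", FAM4 = "q2")
  )
  # family-11-like: all three affected sibs carry, unaffected relative does not
  v11 <- make_variant("ATR", "stop_gained",
                      c(p1 = 1, p2 = 1, p3 = 1, p4 = 0, q1 = 0, q2 = 0, r1 = 0), pos = 1)
  # family-4-like: affected proband carries, one unaffected sibling also carries
  v4 <- make_variant("PALB2", "frameshift_variant",
                     c(p1 = 0, p2 = 0, p3 = 0, p4 = 0, q1 = 1, q2 = 1, r1 = 0), pos = 2)
  # an affected member without the variant breaks segregation
  vfail <- make_variant("X1", "stop_gained",
                        c(p1 = 1, p2 = 0, p3 = 1, p4 = 0, q1 = 0, q2 = 0, r1 = 0), pos = 3)
  seg <- segregation_check(make_variants(v11, v4, vfail), ped)
  status_of <- function(vid, fam) seg$status[seg$variant_id == vid & seg$family_id == fam]
  expect_equal(status_of(v11$variant_id, "FAM11"), "segregates")
  expect_equal(status_of(v4$variant_id, "FAM4"), "segregates")
  expect_equal(status_of(vfail$variant_id, "FAM11"), "fails")
  # a single-member family is uninformative regardless of carriage
  expect_equal(status_of(v11$variant_id, "FAM9"), "uninformative")
})
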
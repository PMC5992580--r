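test_that("consequence classification maps the six LoF categories and ranks severity", {
  expect_equal(classify_consequence("frameshift_variant"), "LOF")
  expect_equal(classify_consequence("splice_acceptor_variant"), "LOF")
  expect_equal(
    classify_consequence(c("stop_gained", "stop_lost", "start_lost",
                           "splice_donor_variant")),
    rep("LOF", 4)
  )
  expect_equal(classify_consequence("missense_variant"), "MISSENSE")
  expect_equal(classify_consequence("inframe_deletion"), "INFRAME_INDEL")
  expect_equal(classify_consequence("synonymous_variant"), "OTHER")
  expect_equal(classify_consequence("some_unseen_term"), "OTHER")
  # compound annotations take the most severe class
  expect_equal(classify_consequence("missense_variant&splice_region_variant"),
               "MISSENSE")
  expect_equal(classify_consequence("stop_gained&missense_variant"), "LOF")
  expect_equal(classify_consequence("intron_variant,inframe_insertion"),
               "INFRAME_INDEL")
  expect_error(classify_consequence(""), "non-empty")
})

test_that("protein-affecting rule honours predictor concordance settings", {
  v <- make_variants(
    make_variant("A", "stop_gained", c(s1 = 1), sift = "tolerated", polyphen = "benign"),
    make_variant("B", "missense_variant", c(s1 = 1), sift = "deleterious",
                 polyphen = "probably_damaging"),
    make_variant("C", "missense_variant", c(s1 = 1), sift = "deleterious",
                 polyphen = "possibly_damaging"),
    make_variant("D", "missense_variant", c(s1 = 1), sift = "deleterious",
                 polyphen = "benign"),
    make_variant("E", "missense_variant", c(s1 = 1), sift = "tolerated",
                 polyphen = "benign"),
    make_variant("F", "inframe_deletion", c(s1 = 1)),
    make_variant("G", "synonymous_variant", c(s1 = 1)),
    make_variant("H", "missense_variant", c(s1 = 1), sift = "unknown",
                 polyphen = "probably_damaging")
  )
  expect_equal(is_protein_affecting(v),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(is_protein_affecting(v, missense_rule = "either"),
               c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(is_protein_affecting(v, possibly_damaging_counts = FALSE)[3], FALSE)
  expect_equal(is_protein_affecting(v, keep_inframe = FALSE)[6], FALSE)
})

test_that("the toy VCF parses with per-allele annotations and allele counts", {
  v <- read_cohort_vcf(toy_vcf_path())
  expect_equal(nrow(v), 40)
  expect_equal(names(v$genotypes[[1]]), c("A1", "A2", "U1", "B1", "U2"))
  expect_equal(v$gene, sprintf("GENE%02d", 1:40))
  # hom-alt counts two alleles; half-missing counts the observed allele
  expect_equal(unname(v$genotypes[[4]]["B1"]), 2L)
  expect_equal(unname(v$genotypes[[26]]["A1"]), 1L)
  expect_true(all(is.na(v$genotypes[[8]])))
  # VEP-style parentheticals are stripped from predictions
  expect_equal(v$sift[9], "deleterious")
  expect_equal(v$polyphen[9], "probably_damaging")
  expect_true(is.na(v$control_af[3]))
  expect_equal(v$control_af[2], 0.2)
})

test_that("multi-allelic records decompose into per-alt rows", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    paste0("1\t500\t.\tA\tT,G\t.\tPASS\t",
           "CSQ=GX|stop_gained|||0.01,GX|missense_variant|deleterious|benign|0.2",
           "\tGT\t1/2\t0/1")
  ), tmp)
  v <- read_cohort_vcf(tmp)
  expect_equal(nrow(v), 2)
  expect_equal(v$alt, c("T", "G"))
  expect_equal(v$consequence, c("LOF", "MISSENSE"))
  expect_equal(v$control_af, c(0.01, 0.2))
  expect_equal(unname(v$genotypes[[1]]), c(1L, 1L))  # allele T per sample
  expect_equal(unname(v$genotypes[[2]]), c(1L, 0L))  # allele G per sample
})

test_that("cohort filtering retains exactly the hand-traced candidate set", {
  v <- read_cohort_vcf(toy_vcf_path())
  ped <- read_pedigree(toy_ped_path())
  expect_warning(f <- filter_variants(v, ped), "all genotypes missing")
  kept <- sprintf("GENE%02d", c(1, 4, 5, 6, 9, 10, 18, 19, 23, 24, 26, 27,
                                29, 30, 31, 34, 35, 36, 38))
  expect_equal(f$gene, kept)
  log <- filter_log(f)
  expect_equal(log$rule, c("all_genotypes_missing", "common_in_controls",
                           "not_protein_affecting", "no_affected_carrier"))
  expect_equal(log$removed, c(1L, 5L, 11L, 4L))
  expect_equal(log$remaining, c(39L, 34L, 23L, 19L))
  expect_true(all(f$affected_carriers >= 1))
})

test_that("filtering is idempotent and monotone in the rarity threshold", {
  cfg <- simulation_config(n_genes = 150, seed = 11)
  sim <- simulate_cohort(cfg)
  f1 <- filter_variants(sim$variants, sim$pedigree)
  f2 <- filter_variants(f1, sim$pedigree)
  expect_equal(f2$variant_id, f1$variant_id)
  ids_strict <- filter_variants(sim$variants, sim$pedigree,
                                max_control_af = 0.01)$variant_id
  ids_default <- f1$variant_id
  ids_loose <- filter_variants(sim$variants, sim$pedigree,
                               max_control_af = 0.5)$variant_id
  expect_true(all(ids_strict %in% ids_default))
  expect_true(all(ids_default %in% ids_loose))
})

test_that("filtering rejects samples missing from the pedigree and empty case sets", {
  v <- make_variant("A", "stop_gained", c(zz = 1))
  ped <- make_ped(list(FAM1 = "s1"))
  expect_error(filter_variants(v, ped), "absent from pedigree")
  ped0 <- make_ped(list(), unaffected = list(FAM1 = "zz"))
  expect_error(filter_variants(v, ped0), "no affected samples")
})
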
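#' Configuration for the synthetic family-cohort simulator
#'
#' Defaults emulate the study design the pipeline targets: 22 families
#' contributing 28 affected and 11 unaffected sequenced members (mostly one
#' affected per family, a few families with 2-4 and sequenced unaffected
#' relatives), a 503-individual European-style control panel, a
#' 1000-gene universe, and a planted signal: a 20-gene set whose
#' loss-of-function rate in affected individuals is
#' `planted_rate_multiplier` times the background, 8 of whose genes form a
#' clique in the interaction network (mirroring a physically interacting
#' DNA-repair cluster).
#'
#' `background_lof_rate` is the per-gene, per-individual probability of
#' carrying a rare loss-of-function allele (default 0.015 — of the order of
#' aggregate rare LoF carriage per gene in population panels at the
#' permissive end, chosen by a design-stage power analysis so each planted
#' gene reaches the post-filter candidate set in ~96% of cohorts and the
#' planted clique is reliably recoverable). Planted
#' variants are family-private and near-absent from the reference panel
#' (mimicking novel LoF variants); background allele frequencies straddle
#' the 0.05 rarity threshold so each filter rule is exercised.
#'
#' @param n_families Number of families (default 22).
#' @param affected_per_family,unaffected_per_family Integer vectors of
#'   sequenced members per family (recycled/truncated to `n_families`).
#' @param n_control Control-panel size (default 503).
#' @param n_genes Gene-universe size (default 1000).
#' @param background_lof_rate Per-gene per-individual rare-LoF carrier
#'   probability (default 0.015).
#' @param planted_term_genes Size of the planted gene set (default 20).
#' @param planted_clique Number of planted genes wired into a network clique
#'   (default 8).
#' @param planted_rate_multiplier Fold increase of the LoF rate in planted
#'   genes for affected individuals (default 8).
#' @param p_damaging_missense,p_benign_missense,p_common,p_synonymous
#'   Per-gene probabilities of carrying, respectively, a rare
#'   deleterious+damaging missense variant, a rare benign missense variant,
#'   a common (AF > 0.05) protein-affecting variant, and a synonymous
#'   variant — decoys that exercise each filter rule.
#' @param p_af_missing Fraction of rare background variants with no control
#'   AF annotation (absent from the panel).
#' @param n_hypervariable Number of hypervariable genes (default 10): genes
#'   carrying `hypervariable_variants` rare protein-affecting variants each,
#'   broadly carried in the healthy population — the decoys the top-1%
#'   hypervariable exclusion is designed to remove (they would otherwise
#'   dominate candidate lists, as mucin/HLA-type genes do in real exomes).
#' @param hypervariable_variants Rare protein-affecting variants per
#'   hypervariable gene (default 15, alternating loss-of-function and
#'   damaging missense, population allele frequencies 0.01-0.04).
#' @param n_decoy_terms Number of decoy gene sets in the annotation (default
#'   49; sizes straddle the 10-200 eligibility window).
#' @param avg_degree Mean degree of the random background interaction
#'   network (default 1).
#' @param seed Integer seed; every simulation is deterministic given it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_families = 22,
                              affected_per_family = c(2, 2, 1, 1, 1, 1, 2, 1, 1, 1,
                                                      4, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                                                      1, 1),
                              unaffected_per_family = c(0, 4, 0, 2, 0, 0, 0, 0, 0, 2,
                                                        1, 0, 0, 0, 0, 0, 0, 0, 1, 0,
                                                        1, 0),
                              n_control = 503,
                              n_genes = 1000,
                              background_lof_rate = 0.015,
                              planted_term_genes = 20,
                              planted_clique = 8,
                              planted_rate_multiplier = 8,
                              p_damaging_missense = 0.5,
                              p_benign_missense = 0.3,
                              p_common = 0.3,
                              p_synonymous = 0.5,
                              p_af_missing = 0.1,
                              n_hypervariable = 10,
                              hypervariable_variants = 15,
                              n_decoy_terms = 49,
                              avg_degree = 1,
                              seed = 1L) {
  aff <- rep_len(affected_per_family, n_families)
  unaff <- rep_len(unaffected_per_family, n_families)
  if (any(aff + unaff < 1) || sum(aff) < 1) {
    stop("every family needs >= 1 sequenced member and >= 1 affected overall",
         call. = FALSE)
  }
  stopifnot(background_lof_rate > 0, background_lof_rate <= 1,
            planted_clique <= planted_term_genes,
            planted_term_genes + n_hypervariable <= n_genes,
            planted_rate_multiplier >= 0)
  structure(list(
    n_families = n_families, affected_per_family = aff,
    unaffected_per_family = unaff, n_control = n_control, n_genes = n_genes,
    background_lof_rate = background_lof_rate,
    planted_term_genes = planted_term_genes, planted_clique = planted_clique,
    planted_rate_multiplier = planted_rate_multiplier,
    p_damaging_missense = p_damaging_missense,
    p_benign_missense = p_benign_missense, p_common = p_common,
    p_synonymous = p_synonymous, p_af_missing = p_af_missing,
    n_hypervariable = n_hypervariable,
    hypervariable_variants = hypervariable_variants,
    n_decoy_terms = n_decoy_terms, avg_degree = avg_degree,
    seed = as.integer(seed)
  ), class = "sim_config")
}

sim_genes <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))
sim_planted_genes <- function(cfg) sim_genes(cfg)[seq_len(cfg$planted_term_genes)]
sim_hyper_genes <- function(cfg) {
  if (cfg$n_hypervariable == 0) return(character())
  utils::tail(sim_genes(cfg), cfg$n_hypervariable)
}
sim_planted_term <- "TERM_PLANTED"

with_sim_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

lof_terms <- c("stop_gained", "stop_lost", "start_lost",
               "splice_acceptor_variant", "splice_donor_variant",
               "frameshift_variant")

#' Simulate an annotated family cohort with a planted gene-set signal
#'
#' Builds a pedigree (two unsequenced founders per family, sequenced
#' affected/unaffected siblings), a background variant universe (rare LoF,
#' rare damaging and benign missense, common, and synonymous variants per
#' gene), drops founder alleles through the pedigree by Mendelian
#' transmission, and plants family-private loss-of-function variants in the
#' planted genes at `planted_rate_multiplier` times the background carrier
#' rate in affected members (transmission to affected siblings is
#' conditioned on carriage — affection is caused by the planted allele;
#' unaffected siblings inherit Mendelianly). Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `variants` (same schema as [read_cohort_vcf()]),
#'   `pedigree` (sequenced members plus founder rows with unknown
#'   phenotype), and `truth` — a ledger with the planted term id, planted
#'   gene list, per-variant provenance, and the expected family-deduplicated
#'   count of each planted variant.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, 0L, {
    genes <- sim_genes(cfg)
    planted <- sim_planted_genes(cfg)

    ped <- sim_pedigree(cfg)
    kids <- ped[!ped$founder, ]
    founders <- ped[ped$founder, ]

    uni <- sim_variant_universe(cfg, genes)

    # founder dosages: one column per founder, Mendelian drop to children
    fd <- matrix(
      stats::rbinom(nrow(uni) * nrow(founders), 2, rep(uni$pop_af, nrow(founders))),
      nrow = nrow(uni)
    )
    colnames(fd) <- founders$sample_id
    transmit <- function(parent_dose) stats::rbinom(length(parent_dose), 1, parent_dose / 2)
    geno <- matrix(0L, nrow(uni), nrow(kids),
                   dimnames = list(NULL, kids$sample_id))
    for (j in seq_len(nrow(kids))) {
      geno[, j] <- transmit(fd[, kids$father[j]]) + transmit(fd[, kids$mother[j]])
    }

    # planted family-private LoF variants supply the excess over the
    # background rate, so multiplier = 1 is exactly the null model
    p_plant <- min(1, max(0, cfg$planted_rate_multiplier - 1) *
                     cfg$background_lof_rate)
    fam_ids <- unique(ped$family_id)
    plant_grid <- tidyr::expand_grid(family_id = fam_ids, gene = planted)
    plant_grid <- plant_grid[stats::runif(nrow(plant_grid)) < p_plant, ]
    planted_rows <- NULL
    if (nrow(plant_grid) > 0) {
      planted_rows <- purrr::pmap(plant_grid, function(family_id, gene) {
        fam_kids <- kids[kids$family_id == family_id, ]
        g <- stats::setNames(integer(nrow(kids)), kids$sample_id)
        g[fam_kids$sample_id] <- ifelse(fam_kids$affected, 1L,
                                        stats::rbinom(nrow(fam_kids), 1, 0.5))
        gi <- match(gene, genes)
        tibble::tibble(
          gene = gene,
          pos = gi * 100000L + 99000L + match(family_id, fam_ids),
          ref = "G", alt = "T",
          raw_consequence = sample(lof_terms, 1),
          sift = "unknown", polyphen = "unknown",
          pop_af = 0.0002,
          control_af = dplyr::if_else(stats::runif(1) < 0.8, NA_real_, 0.0005),
          genotypes = list(g),
          planted = TRUE, planted_family = family_id
        )
      })
      planted_rows <- dplyr::bind_rows(planted_rows)
    }

    bg <- dplyr::mutate(
      uni,
      genotypes = purrr::map(seq_len(nrow(uni)), ~ geno[.x, ]),
      planted = FALSE, planted_family = NA_character_
    )
    all_var <- dplyr::bind_rows(bg, planted_rows)
    all_var <- dplyr::mutate(
      all_var,
      chrom = as.character((match(.data$gene, genes) - 1L) %% 22L + 1L),
      variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
      consequence = classify_consequence(.data$raw_consequence)
    )
    all_var <- dplyr::arrange(all_var, as.integer(.data$chrom), .data$pos)

    variants <- dplyr::select(all_var, "variant_id", "chrom", "pos", "ref",
                              "alt", "gene", "raw_consequence", "consequence",
                              "sift", "polyphen", "control_af", "genotypes")

    ped_out <- dplyr::select(ped, "family_id", "sample_id", "father", "mother",
                             "sex", "affected")

    fam_of <- stats::setNames(kids$family_id, kids$sample_id)
    aff_ids <- kids$sample_id[kids$affected]
    expected_dedup <- purrr::map_int(all_var$genotypes[all_var$planted], function(g) {
      carriers <- names(g)[!is.na(g) & g >= 1]
      dplyr::n_distinct(fam_of[intersect(carriers, aff_ids)])
    })
    truth <- list(
      planted_term_id = sim_planted_term,
      planted_genes = planted,
      clique_genes = planted[seq_len(cfg$planted_clique)],
      hypervariable_genes = sim_hyper_genes(cfg),
      provenance = tibble::tibble(
        variant_id = all_var$variant_id,
        gene = all_var$gene,
        planted = all_var$planted,
        planted_family = all_var$planted_family
      ),
      planted_dedup = tibble::tibble(
        variant_id = all_var$variant_id[all_var$planted],
        n_families = expected_dedup
      ),
      seed = cfg$seed
    )
    list(variants = variants, pedigree = ped_out, truth = truth)
  })
}

sim_pedigree <- function(cfg) {
  rows <- purrr::pmap(
    list(seq_len(cfg$n_families), cfg$affected_per_family,
         cfg$unaffected_per_family),
    function(f, na, nu) {
      fam <- sprintf("F%02d", f)
      founders <- tibble::tibble(
        family_id = fam,
        sample_id = paste0(fam, "_P", 1:2),
        father = "0", mother = "0", sex = 1:2,
        affected = NA, founder = TRUE
      )
      kids <- tibble::tibble(
        family_id = fam,
        sample_id = c(sprintf("%s_A%d", fam, seq_len(na)),
                      if (nu > 0) sprintf("%s_U%d", fam, seq_len(nu))),
        father = paste0(fam, "_P1"), mother = paste0(fam, "_P2"),
        sex = rep_len(c(1L, 2L), na + nu),
        affected = c(rep(TRUE, na), rep(FALSE, nu)),
        founder = FALSE
      )
      dplyr::bind_rows(founders, kids)
    }
  )
  dplyr::bind_rows(rows)
}

# Background variant universe: per-gene decoys exercising every filter rule.
sim_variant_universe <- function(cfg, genes) {
  r <- cfg$background_lof_rate
  n <- cfg$n_genes
  base_pos <- (seq_len(n)) * 100000L
  mk <- function(keep, offset, ref, alt, csq, sift, poly, af) {
    idx <- which(keep)
    tibble::tibble(
      gene = genes[idx], pos = base_pos[idx] + offset,
      ref = ref, alt = alt, raw_consequence = csq,
      sift = sift, polyphen = poly, pop_af = af[idx]
    )
  }
  jitter_af <- function(center) center * stats::runif(n, 0.5, 1.5)
  af_lof <- jitter_af(r / 2)
  af_mis <- jitter_af(r / 2)
  af_ben <- jitter_af(r)
  af_common <- stats::runif(n, 0.06, 0.5)
  af_syn <- stats::runif(n, 0.001, 0.5)
  uni <- dplyr::bind_rows(
    mk(rep(TRUE, n), 10L, "A", "T",
       sample(lof_terms, n, replace = TRUE), "unknown", "unknown", af_lof),
    mk(stats::runif(n) < cfg$p_damaging_missense, 20L, "C", "G",
       "missense_variant", "deleterious", "probably_damaging", af_mis),
    mk(stats::runif(n) < cfg$p_benign_missense, 30L, "G", "A",
       "missense_variant", "tolerated", "benign", af_ben),
    mk(stats::runif(n) < cfg$p_common, 40L, "T", "C",
       "missense_variant", "deleterious", "probably_damaging", af_common),
    mk(stats::runif(n) < cfg$p_synonymous, 50L, "A", "G",
       "synonymous_variant", "unknown", "unknown", af_syn)
  )
  # hypervariable genes: many rare protein-affecting variants each, carried
  # broadly in the healthy population -- the phenomenon the top-1% exclusion
  # rule exists to remove
  hyper <- sim_hyper_genes(cfg)
  if (length(hyper) > 0 && cfg$hypervariable_variants > 0) {
    hv <- cfg$hypervariable_variants
    hyper_rows <- tidyr::expand_grid(gene = hyper, slot = seq_len(hv))
    hyper_rows <- dplyr::mutate(
      hyper_rows,
      pos = base_pos[match(.data$gene, genes)] + 60L + .data$slot,
      ref = "C", alt = "T",
      raw_consequence = dplyr::if_else(.data$slot %% 2L == 1L,
                                       sample(lof_terms, dplyr::n(), replace = TRUE),
                                       "missense_variant"),
      sift = dplyr::if_else(.data$slot %% 2L == 1L, "unknown", "deleterious"),
      polyphen = dplyr::if_else(.data$slot %% 2L == 1L, "unknown",
                                "probably_damaging"),
      pop_af = stats::runif(dplyr::n(), 0.01, 0.04)
    )
    uni <- dplyr::bind_rows(uni, dplyr::select(hyper_rows, -"slot"))
  }
  # annotation AFs are rounded the way real panel annotations are printed
  dplyr::mutate(
    uni,
    control_af = dplyr::if_else(
      .data$pop_af < 0.05 & stats::runif(nrow(uni)) < cfg$p_af_missing,
      NA_real_, round(.data$pop_af, 6)
    )
  )
}

#' Simulate an aggregated control-panel loss-of-function table
#'
#' Per-gene rare loss-of-function allele counts for `n_control` unrelated
#' individuals at the background rate — no planted effect, standing in for a
#' comparably filtered external reference panel. Deterministic given
#' `cfg$seed` (a distinct stream from the cohort's).
#'
#' @param cfg A [simulation_config()].
#' @return A control-count tibble (`gene`, `allele_count`, `cohort_size`).
#' @export
simulate_control_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, 1000003L, {
    genes <- sim_genes(cfg)
    q <- rep(cfg$background_lof_rate / 2, cfg$n_genes)
    # hypervariable genes carry ceiling(hv/2) rare LoF variants at mean
    # allele frequency 0.025 in the healthy population
    hyper <- sim_hyper_genes(cfg)
    q[match(hyper, genes)] <- q[match(hyper, genes)] +
      ceiling(cfg$hypervariable_variants / 2) * 0.025
    tibble::tibble(
      gene = genes,
      allele_count = stats::rbinom(cfg$n_genes, 2L * cfg$n_control, q),
      cohort_size = cfg$n_control
    )
  })
}

#' Simulate an interaction network and gene-set annotations
#'
#' A sparse random background network over the gene universe plus a planted
#' clique wiring the first `planted_clique` planted genes together; gene-set
#' annotations containing the planted term (all planted genes) and decoy
#' terms of mixed sizes, including sizes outside the 10-200 eligibility
#' window. Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `network` (edge tibble) and `gene_sets` (tibble as from
#'   [read_gene_sets()]).
#' @export
simulate_network_and_terms <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, 2000003L, {
    genes <- sim_genes(cfg)
    planted <- sim_planted_genes(cfg)
    clique <- planted[seq_len(cfg$planted_clique)]

    g <- igraph::sample_gnp(cfg$n_genes,
                            p = min(1, cfg$avg_degree / (cfg$n_genes - 1)))
    el <- igraph::as_edgelist(g)
    edges <- tibble::tibble(from = genes[el[, 1]], to = genes[el[, 2]])
    clique_edges <- utils::combn(clique, 2)
    edges <- dplyr::bind_rows(
      edges, tibble::tibble(from = clique_edges[1, ], to = clique_edges[2, ])
    )
    key <- purrr::map2_chr(edges$from, edges$to,
                           ~ paste(sort(c(.x, .y)), collapse = "\r"))
    edges <- dplyr::select(
      dplyr::distinct(dplyr::mutate(edges, .key = key), .data$.key,
                      .keep_all = TRUE),
      "from", "to")

    decoy_sizes <- c(5, 8, 300, 250,
                     sample(10:200, max(0, cfg$n_decoy_terms - 4), replace = TRUE))
    decoy_sizes <- decoy_sizes[seq_len(cfg$n_decoy_terms)]
    sets <- tibble::tibble(
      term_id = c(sim_planted_term,
                  sprintf("TERM%04d", seq_len(cfg$n_decoy_terms))),
      genes = c(list(planted),
                purrr::map(decoy_sizes, ~ sample(genes, min(.x, cfg$n_genes))))
    )
    sets$term_size <- lengths(sets$genes)
    list(network = edges,
         gene_sets = dplyr::select(sets, "term_id", "term_size", "genes"))
  })
}

#' Write a full synthetic input bundle to disk
#'
#' Emits every file the pipeline consumes — annotated VCF, PED, interaction
#' edge list, GMT annotation, control-count TSV — plus a JSON truth ledger,
#' all under one directory. Byte-identical across runs with the same
#' configuration.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly-ready to feed
#'   [run_pipeline()].
#' @export
simulate_study_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(cfg)
  nett <- simulate_network_and_terms(cfg)
  ctrl <- simulate_control_panel(cfg)

  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "cohort.ped"),
    edges = file.path(dir, "network_edges.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    control = file.path(dir, "control_lof_counts.tsv"),
    truth = file.path(dir, "truth_ledger.json")
  )
  write_cohort_vcf(sim$variants, paths$vcf)
  write_pedigree(sim$pedigree, paths$ped)
  readr::write_tsv(nett$network, paths$edges, col_names = FALSE)
  writeLines(
    purrr::map2_chr(nett$gene_sets$term_id, nett$gene_sets$genes,
                    ~ paste(c(.x, .x, .y), collapse = "\t")),
    paths$gmt
  )
  readr::write_tsv(ctrl, paths$control)
  jsonlite::write_json(
    list(planted_term_id = sim$truth$planted_term_id,
         planted_genes = sim$truth$planted_genes,
         clique_genes = sim$truth$clique_genes,
         seed = cfg$seed,
         planted_dedup = sim$truth$planted_dedup),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  paths
}
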
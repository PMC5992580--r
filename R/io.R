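#' Read an annotated multi-sample cohort VCF into a variant tibble
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) carrying VEP/CSQ-style per-allele
#' annotations and returns one row per alt allele. Multi-allelic records are
#' decomposed: the i-th `&`-free CSQ entry annotates the i-th alt allele, and
#' per-sample allele counts are recomputed per alt. Half-missing genotypes
#' (`./1`) count observed alleles only; fully missing genotypes are `NA`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param csq_fields Order of the annotation sub-fields inside each CSQ entry.
#' @param csq_tag INFO tag holding the annotation (default `"CSQ"`).
#' @return A tibble with columns `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `raw_consequence`, `consequence`, `sift`, `polyphen`,
#'   `control_af`, and a `genotypes` list-column of named integer allele
#'   counts (sample id -> 0/1/2/NA).
#' @export
read_cohort_vcf <- function(path,
                            csq_fields = c("SYMBOL", "Consequence", "SIFT",
                                           "PolyPhen", "EUR_AF"),
                            csq_tag = "CSQ") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)

  csq <- stringr::str_match(fix$INFO, paste0("(?:^|;)", csq_tag, "=([^;]*)"))[, 2]

  rows <- purrr::pmap(
    list(fix$CHROM, fix$POS, fix$REF, fix$ALT, csq, seq_len(nrow(fix))),
    function(chrom, pos, ref, alt_field, csq_field, i) {
      alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
      anns <- if (is.na(csq_field)) character(0) else
        strsplit(csq_field, ",", fixed = TRUE)[[1]]
      gt_row <- if (is.matrix(gt_raw)) gt_raw[i, ] else gt_raw[i]
      purrr::map(seq_along(alts), function(ai) {
        ann <- parse_csq_entry(if (ai <= length(anns)) anns[ai] else NA_character_,
                               csq_fields)
        counts <- allele_counts_for(gt_row, ai)
        names(counts) <- samples
        tibble::tibble(
          chrom = chrom, pos = as.integer(pos), ref = ref, alt = alts[ai],
          gene = ann$gene, raw_consequence = ann$consequence,
          sift = ann$sift, polyphen = ann$polyphen, control_af = ann$af,
          genotypes = list(counts)
        )
      })
    }
  )
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out <- dplyr::mutate(
    out,
    variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
    consequence = classify_consequence(.data$raw_consequence),
    .before = 1
  )
  dplyr::relocate(out, "variant_id", "chrom", "pos", "ref", "alt", "gene",
                  "raw_consequence", "consequence")
}

parse_csq_entry <- function(entry, csq_fields) {
  vals <- if (is.na(entry)) rep(NA_character_, length(csq_fields)) else {
    v <- strsplit(entry, "|", fixed = TRUE)[[1]]
    length(v) <- length(csq_fields)
    v
  }
  names(vals) <- csq_fields
  norm <- function(x) {
    x <- tolower(stringr::str_remove(x, "\\(.*\\)$"))
    dplyr::if_else(is.na(x) | !nzchar(x), "unknown", x)
  }
  af <- suppressWarnings(as.numeric(vals[["EUR_AF"]]))
  list(
    gene = if (is.na(vals[["SYMBOL"]]) || !nzchar(vals[["SYMBOL"]])) NA_character_
           else vals[["SYMBOL"]],
    consequence = if (is.na(vals[["Consequence"]]) || !nzchar(vals[["Consequence"]]))
      "intergenic_variant" else vals[["Consequence"]],
    sift = norm(vals[["SIFT"]]),
    polyphen = norm(vals[["PolyPhen"]]),
    af = af
  )
}

# Allele count of alt index `ai` per sample; half-missing counts observed
# alleles only, fully missing -> NA.
allele_counts_for <- function(gt, ai) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    obs <- alleles[alleles != "."]
    if (length(obs) == 0) return(NA_integer_)
    sum(obs == as.character(ai))
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a 6-column PED pedigree
#'
#' Whitespace-delimited PED: family, individual, father, mother, sex,
#' phenotype (2 = affected, 1 = unaffected, 0/-9 = unknown).
#'
#' @param path Path to a PED file.
#' @return A tibble with columns `family_id`, `sample_id`, `father`, `mother`,
#'   `sex`, `affected` (logical, `NA` when phenotype is unknown).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_table(
    path,
    col_names = c("family_id", "sample_id", "father", "mother", "sex", "phenotype"),
    col_types = readr::cols(.default = readr::col_character(),
                            sex = readr::col_integer(),
                            phenotype = readr::col_integer()),
    comment = "#"
  )
  dplyr::mutate(
    ped,
    affected = dplyr::case_when(.data$phenotype == 2 ~ TRUE,
                                .data$phenotype == 1 ~ FALSE,
                                TRUE ~ NA),
    .keep = "unused"
  )
}

#' Read an undirected gene-interaction edge list
#'
#' Two tab-separated symbol columns (optional further columns, e.g. weights,
#' are ignored). Self-loops are dropped and each unordered pair is kept once.
#'
#' @param path Path to the headerless TSV edge list (`#`-prefixed comment
#'   lines are skipped).
#' @return A tibble with columns `from`, `to` (unordered pairs, deduplicated).
#' @export
read_interaction_network <- function(path) {
  edges <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                           comment = "#")
  edges <- tibble::tibble(from = as.character(edges[[1]]),
                          to = as.character(edges[[2]]))
  edges <- dplyr::filter(edges, .data$from != .data$to)
  key <- purrr::map2_chr(edges$from, edges$to,
                         ~ paste(sort(c(.x, .y)), collapse = "\r"))
  dplyr::distinct(dplyr::mutate(edges, .key = key), .data$.key, .keep_all = TRUE) |>
    dplyr::select("from", "to")
}

#' Read gene-set annotations from a GMT file
#'
#' One named set per line (`id`, description, member symbols), parsed with
#' \code{fgsea::gmtPathways()}.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `term_size`, and a `genes`
#'   list-column of member symbols.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  tibble::tibble(
    term_id = names(sets),
    term_size = lengths(sets),
    genes = purrr::map(sets, unique)
  )
}

#' Read aggregated control-cohort loss-of-function counts
#'
#' TSV with columns `gene`, `allele_count`, `cohort_size`: per-gene
#' loss-of-function allele counts from a comparably filtered reference panel.
#'
#' @param path Path to the TSV.
#' @return A tibble with those columns; `cohort_size` must be constant.
#' @export
read_control_counts <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    allele_count = readr::col_integer(),
    cohort_size = readr::col_integer()
  ), comment = "#")
  if (dplyr::n_distinct(out$cohort_size) != 1) {
    stop("control table must report a single cohort_size", call. = FALSE)
  }
  out
}

#' Read per-proband carrier records from published studies
#'
#' TSV mirroring a published-variant table: one row per reported variant per
#' proband, with columns `study`, `patient_id`, `gene`, `variant`,
#' `consequence` (free-text label), `population`, `diagnosis`, and an
#' optional `excluded` column giving a non-empty reason when the row is
#' excluded from carrier counting.
#'
#' @param path Path to the TSV.
#' @return A tibble of study carrier records.
#' @export
read_study_records <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#")
  needed <- c("study", "patient_id", "gene", "variant", "consequence")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("study records missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"excluded" %in% names(out)) out$excluded <- NA_character_
  out
}

#' Write a variant tibble as an annotated VCF 4.2 file
#'
#' Inverse of [read_cohort_vcf()] for the simulator's output: emits one
#' biallelic record per row with a single-entry CSQ annotation
#' (`SYMBOL|Consequence|SIFT|PolyPhen|EUR_AF`) and unphased diploid GT
#' fields. Round-trips exactly through [read_cohort_vcf()].
#'
#' @param variants Variant tibble as produced by [simulate_cohort()] or
#'   [read_cohort_vcf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, path) {
  samples <- names(variants$genotypes[[1]])
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence annotations. Format: SYMBOL|Consequence|SIFT|PolyPhen|EUR_AF\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt_af <- function(af) ifelse(is.na(af), "",
                                format(af, scientific = FALSE, trim = TRUE,
                                       digits = 15))
  gt_string <- function(counts) {
    vapply(counts, function(g) {
      if (is.na(g)) "./." else c("0/0", "0/1", "1/1")[g + 1]
    }, character(1))
  }
  body <- purrr::pmap_chr(
    list(variants$chrom, variants$pos, variants$ref, variants$alt,
         variants$gene, variants$raw_consequence, variants$sift,
         variants$polyphen, variants$control_af, variants$genotypes),
    function(chrom, pos, ref, alt, gene, csq, sift, poly, af, geno) {
      info <- sprintf("CSQ=%s|%s|%s|%s|%s", gene, csq, sift, poly, fmt_af(af))
      paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT",
              gt_string(geno)), collapse = "\t")
    }
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a pedigree tibble as a 6-column PED file
#'
#' @param pedigree Pedigree tibble (see [read_pedigree()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  lines <- sprintf("%s\t%s\t%s\t%s\t%d\t%d",
                   pedigree$family_id, pedigree$sample_id,
                   pedigree$father, pedigree$mother, pedigree$sex,
                   dplyr::if_else(is.na(pedigree$affected), 0L,
                                  dplyr::if_else(pedigree$affected, 2L, 1L)))
  writeLines(lines, path)
  invisible(path)
}
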
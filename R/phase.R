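#' Parental-origin decision for one family at one SNP
#'
#' A family is informative at a SNP when the placenta is heterozygous and the
#' parental genotypes pin each placental allele to one parent: a homozygous
#' mother fixes the maternal allele (the paternal allele is the other one,
#' provided the father — if genotyped — carries it, else the call is a
#' Mendelian error); with a heterozygous or ungenotyped mother, a homozygous
#' father fixes the paternal allele. Both parents heterozygous, a
#' non-heterozygous placenta, or a duo with heterozygous mother are
#' uninformative. A genotype that is required for the decision but missing
#' yields `missing_data`.
#'
#' @param placenta_gt,mother_gt Genotype vectors
#'   (hom_ref/het/hom_alt/missing).
#' @param father_gt Genotype vector, or `NA` where the family is a duo (no
#'   father sample).
#' @param trio_het_mother_informative Logical: whether a homozygous father
#'   can make the call with a heterozygous/ungenotyped mother (the "at least
#'   one homozygous parent" reading; default `TRUE`).
#' @return Tibble with columns `status` (informative / uninformative /
#'   mendelian_error / missing_data) and `maternal_allele`, `paternal_allele`
#'   (`"ref"`/`"alt"`, `NA` unless informative).
#' @examples
#' classify_family_snp("het", "hom_ref", "het")      # informative: mat ref
#' classify_family_snp("het", "het", NA)             # duo, uninformative
#' classify_family_snp("het", "hom_ref", "hom_ref")  # mendelian error
#' @export
classify_family_snp <- function(placenta_gt, mother_gt, father_gt = NA,
                                trio_het_mother_informative = TRUE) {
  n <- max(length(placenta_gt), length(mother_gt), length(father_gt))
  pl <- norm_gt(rep_len(placenta_gt, n))
  mo <- norm_gt(rep_len(mother_gt, n))
  fa <- norm_gt(rep_len(father_gt, n)) # NA = no father sample (duo)

  hom <- function(g) g %in% c("hom_ref", "hom_alt")
  hom_allele <- function(g) ifelse(g == "hom_ref", "ref",
                                   ifelse(g == "hom_alt", "alt", NA_character_))
  other <- function(a) ifelse(a == "ref", "alt", "ref")

  mo_hom_a <- hom_allele(mo)
  fa_hom_a <- hom_allele(fa)
  # does the father's genotype carry a given allele?
  father_carries <- function(allele) {
    ifelse(is.na(fa) | fa == "het", TRUE, fa_hom_a == allele)
  }

  status <- rep("uninformative", n)
  mat <- rep(NA_character_, n)
  pat <- rep(NA_character_, n)

  pl_missing <- pl == "missing"
  status[pl_missing] <- "missing_data"

  het_pl <- !pl_missing & pl == "het"

  # mother homozygous: maternal allele fixed
  mhom <- het_pl & hom(mo)
  need <- other(mo_hom_a)
  ok_father <- !(!is.na(fa) & fa != "missing" & !father_carries(need))
  status[mhom & ok_father] <- "informative"
  mat[mhom & ok_father] <- mo_hom_a[mhom & ok_father]
  pat[mhom & ok_father] <- need[mhom & ok_father]
  status[mhom & !ok_father] <- "mendelian_error"

  # mother het or ungenotyped: a homozygous father can still decide
  mother_open <- het_pl & !hom(mo)
  fhom <- mother_open & !is.na(fa) & hom(fa)
  if (trio_het_mother_informative) {
    status[fhom] <- "informative"
    pat[fhom] <- fa_hom_a[fhom]
    mat[fhom] <- other(fa_hom_a)[fhom]
  }
  # remaining het-placenta cases with a missing required genotype
  undecided <- het_pl & status == "uninformative"
  mo_missing <- undecided & mo == "missing"
  fa_missing_trio <- undecided & !is.na(fa) & fa == "missing"
  status[mo_missing | (undecided & mo == "het" & fa_missing_trio)] <- "missing_data"

  tibble(status = factor(status, levels = c("informative", "uninformative",
                                            "mendelian_error", "missing_data")),
         maternal_allele = mat, paternal_allele = pat)
}

norm_gt <- function(g) {
  out <- as.character(g)
  out[!is.na(out) & !out %in% GT_LEVELS] <- "missing"
  out
}

#' Call parental origin for every family at every SNP
#'
#' Joins the pedigree to the genotype table and applies
#' [classify_family_snp()] to each (family, SNP) pair. Samples absent from
#' the genotype table at a SNP are treated as missing genotypes.
#'
#' @param genotypes Genotype tibble from [read_genotypes()] or [sim_cohort()].
#' @param pedigree Pedigree tibble from [read_pedigree()].
#' @param snp_ids Optional character vector restricting the SNPs called
#'   (defaults to every SNP in the genotype table).
#' @param config A [poe_config()] (supplies the heterozygous-mother rule
#'   toggle).
#' @return Tibble with columns `family_id`, `snp_id`, `status`,
#'   `maternal_allele`, `paternal_allele`.
#' @export
call_parental_origin <- function(genotypes, pedigree, snp_ids = NULL,
                                 config = poe_config()) {
  config <- as_poe_config(config)
  snp_ids <- snp_ids %||% unique(genotypes$snp_id)
  gt_of <- genotypes |> select("sample", "snp_id", "genotype")
  grid <- tidyr::expand_grid(
    pedigree |> select("family_id", "placenta", "mother", "father"),
    snp_id = snp_ids
  ) |>
    left_join(gt_of, by = c(placenta = "sample", "snp_id")) |>
    rename(placenta_gt = "genotype") |>
    left_join(gt_of, by = c(mother = "sample", "snp_id")) |>
    rename(mother_gt = "genotype") |>
    left_join(gt_of, by = c(father = "sample", "snp_id")) |>
    rename(father_gt = "genotype")
  # genotype missing from the table -> "missing"; absent father sample -> NA
  pl <- ifelse(is.na(grid$placenta_gt), "missing", as.character(grid$placenta_gt))
  mo <- ifelse(is.na(grid$mother_gt), "missing", as.character(grid$mother_gt))
  fa <- ifelse(is.na(grid$father), NA,
               ifelse(is.na(grid$father_gt), "missing", as.character(grid$father_gt)))
  calls <- classify_family_snp(pl, mo, fa,
                               config$trio_het_mother_informative)
  bind_cols(grid |> select("family_id", "snp_id"), calls) |>
    arrange(.data$snp_id, .data$family_id)
}

#' Count informative families per SNP
#'
#' @param calls Output of [call_parental_origin()].
#' @param config A [poe_config()]; a SNP passes with at least
#'   `min_informative_families` informative trios/duos.
#' @return Tibble with columns `snp_id`, `n_informative`, `pass`.
#' @export
count_informative_families <- function(calls, config = poe_config()) {
  config <- as_poe_config(config)
  calls |>
    group_by(.data$snp_id) |>
    summarise(n_informative = sum(.data$status == "informative"),
              .groups = "drop") |>
    mutate(pass = .data$n_informative >= config$min_informative_families)
}
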
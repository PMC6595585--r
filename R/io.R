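#' Read genotypes from a VCF file
#'
#' Reads a VCF 4.x file of array-genotyped SNPs and returns one row per
#' (sample, site) with the genotype decoded to `hom_ref` / `het` / `hom_alt` /
#' `missing`. Genotypes are treated as unphased; parental phase is inferred
#' downstream from trio structure, never from the GT separator. Multi-allelic
#' sites violate the biallelic-SNV contract of the analysis and are dropped
#' with a warning naming them.
#'
#' @param vcf_path Path to a VCF file (plain text or bgzipped).
#' @return A tibble with columns `sample`, `snp_id`, `genotype` (factor with
#'   levels hom_ref, het, hom_alt, missing). The site table (columns `snp_id`,
#'   `chrom`, `pos`, `ref`, `alt`) is attached as attribute `"sites"`; retrieve
#'   it with [snp_sites()].
#' @seealso [snp_sites()], [read_allelic_counts()]
#' @export
read_genotypes <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) {
    warn("VCF contains no sites")
    out <- tibble(sample = character(), snp_id = character(),
                  genotype = factor(character(), levels = GT_LEVELS))
    attr(out, "sites") <- tibble(snp_id = character(), chrom = character(),
                                 pos = integer(), ref = character(),
                                 alt = character())
    return(out)
  }
  multi <- grepl(",", fix$ALT %||% "") |
    nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L | is.na(fix$ALT)
  if (any(multi)) {
    warn(paste0("dropping ", sum(multi),
                " non-biallelic-SNV site(s): ",
                paste(site_label(fix)[multi], collapse = ", ")))
  }
  keep <- !multi
  sites <- tibble(
    snp_id = site_label(fix)[keep],
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  rownames(gt) <- sites$snp_id
  out <- as_tibble(gt, rownames = "snp_id") |>
    tidyr::pivot_longer(-"snp_id", names_to = "sample", values_to = "gt_raw") |>
    mutate(genotype = decode_gt(.data$gt_raw)) |>
    select("sample", "snp_id", "genotype") |>
    arrange(.data$sample, .data$snp_id)
  attr(out, "sites") <- sites
  out
}

site_label <- function(fix) {
  id <- fix$ID
  blank <- is.na(id) | id == "." | id == ""
  id[blank] <- paste0(fix$CHROM[blank], "_", fix$POS[blank])
  id
}

decode_gt <- function(gt_raw) {
  alleles <- strsplit(ifelse(is.na(gt_raw), ".", gt_raw), "[/|]")
  code <- vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == "." | a == "")) return("missing")
    n_alt <- sum(a == "1")
    if (any(!a %in% c("0", "1"))) return("missing")
    c("hom_ref", "het", "hom_alt")[n_alt + 1L]
  }, character(1))
  factor(code, levels = GT_LEVELS)
}

#' Site table of a genotype tibble
#'
#' @param genotypes Output of [read_genotypes()] (or [sim_cohort()]'s
#'   genotype element).
#' @return Tibble with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
snp_sites <- function(genotypes) {
  sites <- attr(genotypes, "sites")
  if (is.null(sites)) abort("genotype table has no \"sites\" attribute")
  sites
}

#' Read a pedigree of placental trios and duos
#'
#' The pedigree links each placenta to its mother and (for trios) father and
#' carries the clinical subgroup and gestational age of the pregnancy. The
#' subgroup vocabulary is closed: first/second trimester terminations
#' (`trim1`, `trim2`), uncomplicated term (`trim3_normal`), preeclampsia
#' (`PE`), gestational diabetes (`GD`), and small-/large-for-gestational-age
#' newborns (`SGA`, `LGA`).
#'
#' @param ped_path Tab-separated file with header columns `family_id`,
#'   `placenta`, `mother`, `father` (`"0"` or empty for duos),
#'   `clinical_group`, `gestational_age_days`.
#' @return A tibble with one row per family; `father` is `NA` for duos.
#' @export
read_pedigree <- function(ped_path) {
  ped <- readr::read_tsv(ped_path, col_types = readr::cols(
    family_id = readr::col_character(), placenta = readr::col_character(),
    mother = readr::col_character(), father = readr::col_character(),
    clinical_group = readr::col_character(),
    gestational_age_days = readr::col_integer()
  ))
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  required <- c("family_id", "placenta", "mother", "father", "clinical_group",
                "gestational_age_days")
  missing_cols <- setdiff(required, names(ped))
  if (length(missing_cols)) {
    abort(paste("pedigree is missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  ped <- as_tibble(ped) |>
    mutate(father = ifelse(is.na(.data$father) | .data$father %in% c("0", ""),
                           NA_character_, .data$father))
  if (anyDuplicated(ped$family_id)) {
    abort(paste("duplicate family_id:",
                paste(unique(ped$family_id[duplicated(ped$family_id)]),
                      collapse = ", ")))
  }
  if (anyDuplicated(ped$placenta)) {
    abort(paste("placenta sample referenced by more than one family:",
                paste(unique(ped$placenta[duplicated(ped$placenta)]),
                      collapse = ", ")))
  }
  bad_group <- setdiff(unique(ped$clinical_group), POE_GROUPS)
  if (length(bad_group)) {
    abort(paste0("unknown clinical_group label(s): ",
                 paste(bad_group, collapse = ", "),
                 "; expected one of ", paste(POE_GROUPS, collapse = ", ")))
  }
  if (any(is.na(ped$placenta) | is.na(ped$mother))) {
    abort("placenta and mother identifiers are required for every family")
  }
  if (any(is.na(ped$gestational_age_days) | ped$gestational_age_days <= 0)) {
    abort("gestational_age_days must be a positive integer")
  }
  ped |>
    mutate(clinical_group = factor(.data$clinical_group, levels = POE_GROUPS))
}

#' Read per-sample per-SNP allelic read counts
#'
#' Consumes the tabulated output of an upstream pileup over the marker SNP
#' positions (one row per placental sample and SNP, reference and alternate
#' read tallies). Pileup generation itself is upstream of this package.
#'
#' @param tsv_path Tab-separated file with header columns `sample`, `snp_id`,
#'   `ref_count`, `alt_count`.
#' @return Tibble with those four columns; counts are non-negative integers.
#' @export
read_allelic_counts <- function(tsv_path) {
  counts <- readr::read_tsv(tsv_path, col_types = readr::cols(
    sample = readr::col_character(), snp_id = readr::col_character(),
    ref_count = readr::col_double(), alt_count = readr::col_double()
  ))
  validate_allelic_counts(counts)
}

validate_allelic_counts <- function(counts) {
  required <- c("sample", "snp_id", "ref_count", "alt_count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols)) {
    abort(paste("allelic counts missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  counts <- as_tibble(counts)
  if (nrow(counts) == 0L) {
    warn("allelic count table is empty")
    return(mutate(counts, ref_count = integer(), alt_count = integer()))
  }
  if (any(counts$ref_count < 0 | counts$alt_count < 0, na.rm = TRUE) ||
      any(is.na(counts$ref_count) | is.na(counts$alt_count)) ||
      any(counts$ref_count %% 1 != 0 | counts$alt_count %% 1 != 0)) {
    abort("ref_count/alt_count must be non-negative integers")
  }
  dup <- duplicated(counts[c("sample", "snp_id")])
  if (any(dup)) {
    abort(paste("duplicate (sample, snp_id) in allelic counts:",
                paste(utils::head(paste(counts$sample[dup], counts$snp_id[dup]),
                                  5), collapse = "; ")))
  }
  mutate(counts, ref_count = as.integer(.data$ref_count),
         alt_count = as.integer(.data$alt_count))
}

#' Read exon intervals from a BED file
#'
#' BED intervals are 0-based half-open; a 1-based SNP position `p` falls in
#' `[start, end)` iff `start < p <= end`. Column 4 must carry the gene
#' identifier.
#'
#' @param bed_path Path to a BED file (no header, >= 4 columns).
#' @return Tibble with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_exon_bed <- function(bed_path) {
  bed <- readr::read_tsv(bed_path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(bed) < 4L) abort("BED file must have at least 4 columns (name = gene)")
  out <- tibble(
    chrom = bed[[1]],
    start = as.integer(bed[[2]]),
    end = as.integer(bed[[3]]),
    gene_id = bed[[4]]
  )
  if (any(is.na(out$start) | is.na(out$end))) {
    abort("BED start/end must be integers")
  }
  bad <- out$start >= out$end
  if (any(bad)) {
    abort(paste0("BED interval with start >= end at line(s): ",
                 paste(which(bad), collapse = ", ")))
  }
  out
}

#' Test exon containment of SNP positions
#'
#' @param pos Integer vector of 1-based positions.
#' @param start,end Parallel vectors (or scalars) of 0-based half-open
#'   interval bounds.
#' @return Logical vector: `start < pos <= end`.
#' @examples
#' snp_in_exon(c(100L, 150L, 200L), 100L, 200L) # FALSE TRUE TRUE
#' @export
snp_in_exon <- function(pos, start, end) {
  start < pos & pos <= end
}

#' Read a gene-level read-count matrix
#'
#' @param tsv_path Tab-separated file: first column `gene_id`, one column of
#'   raw read counts per sample.
#' @return Tibble, genes in rows, one column per sample plus `gene_id`.
#' @export
read_gene_counts <- function(tsv_path) {
  counts <- readr::read_tsv(tsv_path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  if (!"gene_id" %in% names(counts)) abort("gene count table needs a gene_id column")
  num <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (any(num < 0 | num %% 1 != 0)) abort("gene counts must be non-negative integers")
  if (anyDuplicated(counts$gene_id)) abort("duplicate gene_id in gene count table")
  counts
}

#' Write a genotype table to VCF
#'
#' Emits a minimal VCF 4.2 with unphased GT fields, suitable for round-trips
#' through [read_genotypes()]. Used by the cohort simulator.
#'
#' @param genotypes Tibble with `sample`, `snp_id`, `genotype` and a `"sites"`
#'   attribute (as produced by [read_genotypes()] / [sim_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  sites <- snp_sites(genotypes)
  samples <- sort(unique(genotypes$sample))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  wide <- genotypes |>
    mutate(gt = gt_code[as.character(.data$genotype)]) |>
    select("sample", "snp_id", "gt") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "gt",
                       values_fill = "./.")
  wide <- wide[match(sites$snp_id, wide$snp_id), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, sites$snp_id, sites$ref, sites$alt, ".", ".", ".",
    "GT",
    do.call(paste, c(unname(as.list(wide[samples])), sep = "\t")),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
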
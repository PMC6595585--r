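#' Noise model for simulated allelic reads
#'
#' Two nuisance processes shape allele-specific read counts from placental
#' tissue: a small fraction of RNA originating from maternal cells (blood or
#' decidua) admixed with the placental signal, and per-read allele miscalls
#' from sequencing/alignment error. The default contamination fraction of
#' 0.93% matches the median maternal-cell RNA fraction estimated for the kind
#' of placental cohort this simulator emulates.
#'
#' @param contamination_rho Fraction of reads drawn from the mother's own
#'   transcripts rather than the placenta's.
#' @param seq_error_eps Per-read probability that the observed allele is
#'   flipped.
#' @return A list with class `"poe_noise"`.
#' @export
poe_noise <- function(contamination_rho = 0.0093, seq_error_eps = 0.001) {
  if (contamination_rho < 0 || contamination_rho >= 0.5 ||
      seq_error_eps < 0 || seq_error_eps >= 0.5) {
    abort("contamination_rho and seq_error_eps must lie in [0, 0.5)")
  }
  structure(list(contamination_rho = contamination_rho,
                 seq_error_eps = seq_error_eps),
            class = "poe_noise")
}

#' Simulate parental genotypes under Hardy-Weinberg equilibrium
#'
#' Draws independent genotypes with frequencies p^2 / 2pq / q^2, where q is
#' the minor (alt) allele frequency.
#'
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param n_individuals Number of genotypes to draw.
#' @param seed Optional integer seed (scoped locally; the caller's RNG state
#'   is untouched).
#' @return Factor vector of length `n_individuals` with levels hom_ref, het,
#'   hom_alt, missing.
#' @export
sim_parent_genotypes <- function(maf, n_individuals, seed = NULL) {
  if (length(maf) != 1 || is.na(maf) || maf <= 0 || maf > 0.5) {
    abort("maf must lie in (0, 0.5]")
  }
  if (n_individuals < 1) abort("n_individuals must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  q <- maf
  p <- 1 - q
  gt <- sample(c("hom_ref", "het", "hom_alt"), n_individuals, replace = TRUE,
               prob = c(p^2, 2 * p * q, q^2))
  factor(gt, levels = GT_LEVELS)
}

# P(an allele sampled from this genotype is alt)
gt_alt_dose <- function(gt) {
  c(hom_ref = 0, het = 0.5, hom_alt = 1, missing = NA_real_)[as.character(gt)]
}

#' Simulate Mendelian transmission to a placenta
#'
#' Each conceptus inherits one allele drawn uniformly from the mother's two
#' and one from the father's two; the placental genotype is the unordered
#' pair. Vectorised over families.
#'
#' @param mother_gt,father_gt Parental genotype vectors (non-missing).
#' @param seed Optional integer seed.
#' @return Tibble with columns `placenta_gt` (factor), `maternal_allele`,
#'   `paternal_allele` (`"ref"`/`"alt"`).
#' @export
sim_offspring <- function(mother_gt, father_gt, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  m_dose <- gt_alt_dose(mother_gt)
  f_dose <- gt_alt_dose(father_gt)
  if (anyNA(m_dose) || anyNA(f_dose)) {
    abort("parental genotypes must be non-missing for transmission")
  }
  n <- length(m_dose)
  mat_alt <- rbinom(n, 1L, m_dose)
  pat_alt <- rbinom(n, 1L, f_dose)
  placenta <- factor(c("hom_ref", "het", "hom_alt")[mat_alt + pat_alt + 1L],
                     levels = GT_LEVELS)
  tibble(
    placenta_gt = placenta,
    maternal_allele = ifelse(mat_alt == 1L, "alt", "ref"),
    paternal_allele = ifelse(pat_alt == 1L, "alt", "ref")
  )
}

#' Simulate allele-specific read counts at a SNP
#'
#' Total depth is Poisson with the given mean. Each read originates from the
#' maternal placental allele with probability (1 - rho) * theta, from the
#' paternal placental allele with probability (1 - rho) * (1 - theta), and
#' from contaminating maternal cells with probability rho, where theta is the
#' gene's true maternal transcript share. Contaminant reads carry one of the
#' mother's own two alleles (equiprobable if she is heterozygous). Finally
#' every read's allele is flipped with probability eps. Vectorised over
#' (family, SNP) rows.
#'
#' @param maternal_allele,paternal_allele `"ref"`/`"alt"` vectors for the
#'   transmitted placental alleles.
#' @param mother_gt Mother's genotype vector (source of contaminant reads).
#' @param theta True maternal transcript share, in \[0, 1\] (scalar or vector).
#' @param depth_mean Mean sequencing depth (scalar or vector).
#' @param noise A [poe_noise()] object.
#' @param seed Optional integer seed.
#' @return Tibble with columns `ref_count`, `alt_count`.
#' @export
sim_allelic_reads <- function(maternal_allele, paternal_allele, mother_gt,
                              theta, depth_mean, noise = poe_noise(),
                              seed = NULL) {
  if (any(theta < 0 | theta > 1)) abort("theta must lie in [0, 1]")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(maternal_allele)
  theta <- rep_len(theta, n)
  depth_mean <- rep_len(depth_mean, n)
  rho <- noise$contamination_rho
  eps <- noise$seq_error_eps

  depth <- rpois(n, depth_mean)
  n_contam <- rbinom(n, depth, rho)
  n_mat <- rbinom(n, depth - n_contam, theta)
  n_pat <- depth - n_contam - n_mat

  contam_alt <- rbinom(n, n_contam, gt_alt_dose(mother_gt))
  alt_true <- ifelse(maternal_allele == "alt", n_mat, 0L) +
    ifelse(paternal_allele == "alt", n_pat, 0L) +
    contam_alt
  ref_true <- depth - alt_true
  # symmetric per-read allele flips
  alt_obs <- rbinom(n, alt_true, 1 - eps) + rbinom(n, ref_true, eps)
  tibble(ref_count = as.integer(depth - alt_obs), alt_count = as.integer(alt_obs))
}

#' Gene models for the cohort simulator
#'
#' One row per simulated gene: the true maternal transcript share theta, the
#' number of marker SNPs, their minor allele frequencies, the mean read depth
#' at a SNP, and expression-level parameters for the gene count matrix. The
#' default set mirrors the class composition observed in placental imprinting
#' screens — a minority of imprinted genes (theta near 0 or 1), a band of
#' parentally biased genes, and a biallelic majority — with theta defaults of
#' 0.98 / 0.02 (imprinted maternal / paternal), 0.75 / 0.17 (biased maternal
#' / paternal), and 0.5 (biallelic).
#'
#' @param n_imprinted_mat,n_imprinted_pat,n_biased_mat,n_biased_pat,n_biallelic
#'   Number of genes per class (defaults 3, 8, 4, 10, 0: a 25-gene panel with
#'   the observed imprinted/biased split).
#' @param theta_imprinted_mat,theta_imprinted_pat,theta_biased_mat,theta_biased_pat,theta_biallelic
#'   Maternal transcript share per class.
#' @param n_snps Marker SNPs per gene.
#' @param snp_maf Minor allele frequency of every marker SNP.
#' @param mean_depth Mean read depth at a SNP position.
#' @param gene_length_bp Transcript length used for FPKM.
#' @param mean_expression Mean raw read count per sample in the gene count
#'   matrix.
#' @return Tibble with one row per gene (`gene_id`, `theta`, `true_class`,
#'   `n_snps`, `snp_mafs` list-column, `mean_depth`, `gene_length_bp`,
#'   `mean_expression`).
#' @export
sim_gene_models <- function(n_imprinted_mat = 3, n_imprinted_pat = 8,
                            n_biased_mat = 4, n_biased_pat = 10,
                            n_biallelic = 0,
                            theta_imprinted_mat = 0.98,
                            theta_imprinted_pat = 0.02,
                            theta_biased_mat = 0.75,
                            theta_biased_pat = 0.17,
                            theta_biallelic = 0.5,
                            n_snps = 2L, snp_maf = 0.3, mean_depth = 50,
                            gene_length_bp = 2000L, mean_expression = 500) {
  theta <- c(rep(theta_imprinted_mat, n_imprinted_mat),
             rep(theta_imprinted_pat, n_imprinted_pat),
             rep(theta_biased_mat, n_biased_mat),
             rep(theta_biased_pat, n_biased_pat),
             rep(theta_biallelic, n_biallelic))
  n_genes <- length(theta)
  if (n_genes == 0L) abort("at least one gene is required")
  snps_per_gene <- as.integer(rep_len(n_snps, n_genes))
  tibble(
    gene_id = sprintf("G%03d", seq_len(n_genes)),
    theta = theta,
    true_class = theta_true_class(theta),
    n_snps = snps_per_gene,
    snp_mafs = purrr::map(snps_per_gene, ~ rep_len(snp_maf, .x)),
    mean_depth = rep_len(mean_depth, n_genes),
    gene_length_bp = as.integer(rep_len(gene_length_bp, n_genes)),
    mean_expression = rep_len(mean_expression, n_genes)
  )
}

#' True class implied by a maternal transcript share
#'
#' Applies the classifier's thresholds to the generative theta itself:
#' imprinted if the preferred-allele share exceeds 0.90, biased if it lies in
#' \[0.65, 0.90\], biallelic otherwise.
#'
#' @param theta Numeric vector of maternal transcript shares.
#' @param config A [poe_config()] supplying the thresholds.
#' @return Factor with levels imprinted, biased, biallelic.
#' @export
theta_true_class <- function(theta, config = poe_config()) {
  f <- pmax(theta, 1 - theta)
  cls <- ifelse(f > config$imprinted_threshold, "imprinted",
                ifelse(f >= config$biased_low, "biased", "biallelic"))
  factor(cls, levels = POE_CLASSES)
}

#' Cohort layouts for the simulator
#'
#' The `"table1"` layout reproduces the family structure of the placental
#' cohort the pipeline was designed around: 54 pregnancies across seven
#' clinical subgroups — 8 first-trimester and 6 second-trimester
#' mother-placenta duos, and term groups of 8 (uncomplicated, PE, GD) or
#' 7 trios + 1 duo (SGA, LGA), for 38 trios and 16 duos in total.
#' Gestational ages are spread evenly over each subgroup's observed range.
#'
#' @param layout Layout name; only `"table1"` is built in.
#' @return Tibble with columns `family_id`, `clinical_group`, `has_father`,
#'   `gestational_age_days`.
#' @export
cohort_layout <- function(layout = "table1") {
  if (!identical(layout, "table1")) abort("unknown layout; only \"table1\" is built in")
  groups <- tibble(
    clinical_group = POE_GROUPS,
    n_trio = c(0L, 0L, 8L, 7L, 7L, 8L, 8L),
    n_duo = c(8L, 6L, 0L, 1L, 1L, 0L, 0L),
    ga_min = c(51, 126, 260, 264, 275, 260, 268),
    ga_max = c(81, 167, 291, 289, 288, 271, 284)
  )
  fam <- groups |>
    rowwise() |>
    reframe(
      clinical_group = .data$clinical_group,
      has_father = rep(c(TRUE, FALSE), c(.data$n_trio, .data$n_duo)),
      gestational_age_days = as.integer(round(seq(.data$ga_min, .data$ga_max,
                                                  length.out = .data$n_trio + .data$n_duo)))
    )
  fam |>
    mutate(family_id = sprintf("F%02d", row_number()),
           clinical_group = factor(.data$clinical_group, levels = POE_GROUPS)) |>
    select("family_id", "clinical_group", "has_father", "gestational_age_days")
}

#' Simulate a trio/duo cohort with allele-specific reads and ground truth
#'
#' Generates, for every gene and marker SNP, Hardy-Weinberg parental
#' genotypes, Mendelian transmission to the placenta, and allele-specific
#' read counts under the gene's true maternal share theta with maternal-cell
#' contamination and sequencing error (see [sim_allelic_reads()]). Duos are
#' created by drawing a father and then hiding him from the genotype and
#' pedigree outputs, so the truth ledger can score duo informativeness rules.
#' A gene count matrix with lognormal library-size variation is emitted for
#' the expression filter.
#'
#' @param genes Gene models from [sim_gene_models()].
#' @param layout Family layout from [cohort_layout()].
#' @param noise A [poe_noise()] object.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param out_dir Optional directory; when given, writes `genotypes.vcf`,
#'   `pedigree.tsv`, `allelic_counts.tsv`, `gene_counts.tsv`, `exons.bed` and
#'   `truth.tsv` there.
#' @return A list of class `"poe_cohort"` with elements `genotypes` (tibble +
#'   `"sites"` attribute), `pedigree`, `allelic_counts`, `gene_counts`,
#'   `exons`, and `truth` (list: `genes`, `transmissions`, `seed`).
#' @examples
#' cohort <- sim_cohort(sim_gene_models(n_snps = 1), seed = 1)
#' cohort$truth$genes
#' @export
sim_cohort <- function(genes = sim_gene_models(), layout = cohort_layout(),
                       noise = poe_noise(), seed = 1L, out_dir = NULL) {
  if (nrow(genes) == 0L) abort("at least one gene is required")
  if (nrow(layout) == 0L) abort("at least one family is required")
  withr::local_seed(seed)

  families <- layout |>
    mutate(placenta = paste0(.data$family_id, "_PL"),
           mother = paste0(.data$family_id, "_M"),
           father_sample = paste0(.data$family_id, "_F"))

  snps <- genes |>
    select("gene_id", "theta", "mean_depth", "n_snps", "snp_mafs") |>
    mutate(gene_idx = row_number()) |>
    tidyr::unnest_longer("snp_mafs", values_to = "maf") |>
    group_by(.data$gene_id) |>
    mutate(snp_idx = row_number()) |>
    ungroup() |>
    mutate(
      snp_id = sprintf("rs_%s_%d", .data$gene_id, .data$snp_idx),
      chrom = "chr1",
      # 10 kb per gene, SNPs 100 bp apart inside the gene body
      pos = as.integer(10000L * .data$gene_idx + 100L * .data$snp_idx),
      ref = "A", alt = "G"
    )

  grid <- tidyr::expand_grid(
    families |> select("family_id", "placenta", "mother", "father_sample",
                       "has_father", "clinical_group"),
    snps |> select("snp_id", "gene_id", "maf", "theta", "mean_depth")
  )
  n <- nrow(grid)
  grid$mother_gt <- sim_parent_genotypes_vec(grid$maf, n)
  grid$father_gt <- sim_parent_genotypes_vec(grid$maf, n)
  off <- sim_offspring(grid$mother_gt, grid$father_gt)
  grid <- bind_cols(grid, off)
  reads <- sim_allelic_reads(grid$maternal_allele, grid$paternal_allele,
                             grid$mother_gt, grid$theta, grid$mean_depth,
                             noise = noise)
  grid <- bind_cols(grid, reads)

  sites <- snps |> select("snp_id", "chrom", "pos", "ref", "alt")
  genotypes <- bind_rows(
    grid |> transmute(sample = .data$placenta, snp_id = .data$snp_id,
                      genotype = .data$placenta_gt),
    grid |> transmute(sample = .data$mother, snp_id = .data$snp_id,
                      genotype = .data$mother_gt),
    grid |> filter(.data$has_father) |>
      transmute(sample = .data$father_sample, snp_id = .data$snp_id,
                genotype = .data$father_gt)
  ) |> arrange(.data$sample, .data$snp_id)
  attr(genotypes, "sites") <- sites

  pedigree <- families |>
    transmute(family_id = .data$family_id, placenta = .data$placenta,
              mother = .data$mother,
              father = ifelse(.data$has_father, .data$father_sample, NA_character_),
              clinical_group = .data$clinical_group,
              gestational_age_days = .data$gestational_age_days)

  allelic_counts <- grid |>
    transmute(sample = .data$placenta, snp_id = .data$snp_id,
              ref_count = .data$ref_count, alt_count = .data$alt_count)

  placentas <- families$placenta
  lib_factor <- exp(stats::rnorm(length(placentas), 0, 0.3))
  gene_counts_mat <- t(vapply(seq_len(nrow(genes)), function(g) {
    rpois(length(placentas), genes$mean_expression[g] * lib_factor)
  }, numeric(length(placentas))))
  gene_counts <- bind_cols(
    tibble(gene_id = genes$gene_id),
    as_tibble(matrix(as.integer(gene_counts_mat), nrow = nrow(genes),
                     dimnames = list(NULL, placentas)))
  )

  exons <- snps |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom),
              start = min(.data$pos) - 50L,      # 0-based half-open
              end = max(.data$pos) + 50L, .groups = "drop") |>
    select("chrom", "start", "end", "gene_id")

  truth <- list(
    genes = genes |> select("gene_id", "theta", "true_class"),
    transmissions = grid |>
      transmute(family_id = .data$family_id, snp_id = .data$snp_id,
                gene_id = .data$gene_id,
                maternal_allele = .data$maternal_allele,
                paternal_allele = .data$paternal_allele,
                hidden_father_gt = ifelse(.data$has_father, NA_character_,
                                          as.character(.data$father_gt))),
    seed = seed
  )

  cohort <- structure(
    list(genotypes = genotypes, pedigree = pedigree,
         allelic_counts = allelic_counts, gene_counts = gene_counts,
         exons = exons, truth = truth),
    class = "poe_cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

# HWE draw with per-row MAF (internal, vectorised; uses ambient RNG stream)
sim_parent_genotypes_vec <- function(maf, n) {
  q <- maf
  u <- runif(n)
  p <- 1 - q
  gt <- ifelse(u < p^2, "hom_ref", ifelse(u < p^2 + 2 * p * q, "het", "hom_alt"))
  factor(gt, levels = GT_LEVELS)
}

#' Write a simulated cohort to disk
#'
#' @param cohort A [sim_cohort()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_vcf(cohort$genotypes, file.path(out_dir, "genotypes.vcf"))
  ped_out <- cohort$pedigree |>
    mutate(father = ifelse(is.na(.data$father), "0", .data$father))
  readr::write_tsv(ped_out, file.path(out_dir, "pedigree.tsv"))
  readr::write_tsv(cohort$allelic_counts, file.path(out_dir, "allelic_counts.tsv"))
  readr::write_tsv(cohort$gene_counts, file.path(out_dir, "gene_counts.tsv"))
  readr::write_tsv(cohort$exons, file.path(out_dir, "exons.bed"),
                   col_names = FALSE)
  readr::write_tsv(cohort$truth$transmissions, file.path(out_dir, "truth.tsv"))
  invisible(out_dir)
}

#' @export
print.poe_cohort <- function(x, ...) {
  cat("<poe_cohort>\n")
  cat("  families:", nrow(x$pedigree),
      sprintf("(%d trios, %d duos)\n", sum(!is.na(x$pedigree$father)),
              sum(is.na(x$pedigree$father))))
  cat("  genes:   ", nrow(x$truth$genes), "\n")
  cat("  snps:    ", nrow(snp_sites(x$genotypes)), "\n")
  cat("  seed:    ", x$truth$seed, "\n")
  invisible(x)
}
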
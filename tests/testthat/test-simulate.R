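test_that("parental genotypes follow Hardy-Weinberg frequencies", {
  g <- sim_parent_genotypes(0.5, 1e5, seed = 11)
  expect_lt(abs(mean(g == "het") - 0.5), 0.01)
  g <- sim_parent_genotypes(0.2, 2e5, seed = 12)
  expect_lt(abs(mean(g == "hom_alt") - 0.04), 0.005)
  expect_lt(abs(mean(g == "het") - 0.32), 0.01)
  expect_error(sim_parent_genotypes(0, 10), "maf")
  expect_error(sim_parent_genotypes(0.7, 10), "maf")
})

test_that("Mendelian transmission forces and mixes alleles correctly", {
  off <- sim_offspring(rep("hom_ref", 5), rep("hom_alt", 5), seed = 1)
  expect_true(all(off$placenta_gt == "het"))
  expect_true(all(off$maternal_allele == "ref"))
  expect_true(all(off$paternal_allele == "alt"))

  off <- sim_offspring(rep("hom_ref", 5), rep("hom_ref", 5), seed = 1)
  expect_true(all(off$placenta_gt == "hom_ref"))

  off <- sim_offspring(rep("het", 1e5), rep("het", 1e5), seed = 2)
  expect_lt(abs(mean(off$placenta_gt == "het") - 0.5), 0.01)

  expect_error(sim_offspring("missing", "het"), "non-missing")
})

test_that("allelic reads realize the theta/contamination/error mixture", {
  # pure maternal expression, no noise: zero paternal-allele reads
  r <- sim_allelic_reads(rep("ref", 50), rep("alt", 50), rep("het", 50),
                         theta = 1, depth_mean = 100,
                         noise = poe_noise(0, 0), seed = 3)
  expect_true(all(r$alt_count == 0L))

  # balanced expression: maternal share near 0.5
  r <- sim_allelic_reads("ref", "alt", "het", theta = 0.5, depth_mean = 10000,
                         noise = poe_noise(0, 0), seed = 4)
  expect_lt(abs(r$ref_count / (r$ref_count + r$alt_count) - 0.5), 0.02)

  # contamination from a heterozygous mother shifts the expectation to
  # (1 - rho) * theta + rho * 0.5
  n <- 250
  r <- sim_allelic_reads(rep("ref", n), rep("alt", n), rep("het", n),
                         theta = 0.95, depth_mean = 5000,
                         noise = poe_noise(0.0093, 0), seed = 5)
  share <- sum(r$ref_count) / sum(r$ref_count + r$alt_count)
  expect_gt(sum(r$ref_count + r$alt_count), 1e6)
  expect_lt(abs(share - ((1 - 0.0093) * 0.95 + 0.0093 * 0.5)), 0.002)

  # sequencing error flips symmetric reads: theta=1 with eps leaves ~eps alt
  n <- 200
  r <- sim_allelic_reads(rep("ref", n), rep("alt", n), rep("hom_ref", n),
                         theta = 1, depth_mean = 5000,
                         noise = poe_noise(0, 0.01), seed = 6)
  eps_hat <- sum(r$alt_count) / sum(r$ref_count + r$alt_count)
  expect_lt(abs(eps_hat - 0.01), 0.002)

  expect_error(sim_allelic_reads("ref", "alt", "het", theta = 1.2,
                                 depth_mean = 10), "theta")
})

test_that("the table1 layout reproduces the cohort structure", {
  lay <- cohort_layout()
  expect_equal(nrow(lay), 54L)
  expect_equal(sum(lay$has_father), 38L)
  expect_equal(sum(!lay$has_father), 16L)
  tab <- table(lay$clinical_group)
  expect_equal(as.integer(tab[c("trim1", "trim2", "trim3_normal", "SGA",
                                "LGA", "PE", "GD")]),
               c(8L, 6L, 8L, 8L, 8L, 8L, 8L))
  expect_true(all(lay$gestational_age_days[lay$clinical_group == "trim1"] <= 81))
})

test_that("cohort generation is deterministic and self-consistent", {
  genes <- sim_gene_models(n_snps = 1)
  a <- sim_cohort(genes, seed = 99)
  b <- sim_cohort(genes, seed = 99)
  expect_identical(a$allelic_counts, b$allelic_counts)
  expect_identical(tibble::as_tibble(a$genotypes), tibble::as_tibble(b$genotypes))
  expect_identical(a$truth$transmissions, b$truth$transmissions)
  c <- sim_cohort(genes, seed = 100)
  expect_false(identical(a$allelic_counts, c$allelic_counts))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_error(sim_cohort(genes, layout = cohort_layout()[0, ], seed = 1),
               "at least one family")
})

test_that("written cohort files parse through the readers", {
  cohort <- sim_cohort(sim_gene_models(n_imprinted_mat = 1, n_imprinted_pat = 1,
                                       n_biased_mat = 1, n_biased_pat = 1,
                                       n_biallelic = 1, n_snps = 1),
                       seed = 7)
  d <- withr::local_tempdir()
  write_cohort(cohort, d)
  gt <- read_genotypes(file.path(d, "genotypes.vcf"))
  expect_equal(tibble::as_tibble(gt),
               tibble::as_tibble(cohort$genotypes) |>
                 dplyr::arrange(sample, snp_id))
  ped <- read_pedigree(file.path(d, "pedigree.tsv"))
  expect_equal(ped$family_id, cohort$pedigree$family_id)
  expect_equal(is.na(ped$father), is.na(cohort$pedigree$father))
  counts <- read_allelic_counts(file.path(d, "allelic_counts.tsv"))
  expect_equal(counts, dplyr::arrange(cohort$allelic_counts, sample, snp_id) |>
                 dplyr::mutate(ref_count = as.integer(ref_count),
                               alt_count = as.integer(alt_count)),
               ignore_attr = TRUE)
  expect_equal(read_gene_counts(file.path(d, "gene_counts.tsv"))$gene_id,
               cohort$gene_counts$gene_id)
  expect_equal(read_exon_bed(file.path(d, "exons.bed")), cohort$exons,
               ignore_attr = TRUE)
})

test_that("empirical maternal-read share converges to the mixture mean per gene", {
  # law of large numbers at the cohort level: pooled share over informative
  # families approaches (1-rho)*theta + rho * E[mother-allele share]
  genes <- sim_gene_models(n_imprinted_mat = 1, n_imprinted_pat = 0,
                           n_biased_mat = 0, n_biased_pat = 0, n_biallelic = 0,
                           theta_imprinted_mat = 0.9, n_snps = 4,
                           snp_maf = 0.5, mean_depth = 2000)
  cohort <- sim_cohort(genes, noise = poe_noise(0.02, 0), seed = 21)
  tr <- cohort$truth$transmissions
  counts <- dplyr::inner_join(cohort$allelic_counts,
                              dplyr::mutate(tr, sample = paste0(family_id, "_PL")),
                              by = c("sample", "snp_id"))
  mat <- ifelse(counts$maternal_allele == "ref", counts$ref_count, counts$alt_count)
  tot <- counts$ref_count + counts$alt_count
  # mothers of het placentas average a maternal-allele share of ~the placental
  # maternal allele dose; restrict to het mothers for the closed form 0.5
  mo <- dplyr::filter(
    dplyr::mutate(cohort$genotypes, family_id = sub("_M$", "", sample)),
    grepl("_M$", sample))
  het_mother_keys <- paste(mo$family_id[mo$genotype == "het"],
                           mo$snp_id[mo$genotype == "het"])
  # restrict to heterozygous placentas (distinct parental alleles) with
  # heterozygous mothers, where the contaminant maternal-allele share is 0.5
  keep <- paste(counts$family_id, counts$snp_id) %in% het_mother_keys &
    counts$maternal_allele != counts$paternal_allele
  share <- sum(mat[keep]) / sum(tot[keep])
  expect_lt(abs(share - ((1 - 0.02) * 0.9 + 0.02 * 0.5)), 0.01)
})
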
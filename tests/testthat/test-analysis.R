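informative_call <- function(family, snp, mat = "ref") {
  tibble::tibble(
    family_id = family, snp_id = snp,
    status = factor("informative", levels = c("informative", "uninformative",
                                              "mendelian_error", "missing_data")),
    maternal_allele = mat, paternal_allele = ifelse(mat == "ref", "alt", "ref")
  )
}

test_that("allelic tallies map to parental counts by the call's assignment", {
  counts <- tibble::tibble(sample = "P1", snp_id = "rs1",
                           ref_count = 687L, alt_count = 35L)
  snps <- tibble::tibble(snp_id = "rs1", gene_id = "RTL1")
  ped <- tiny_pedigree()

  pc <- map_counts_to_parents(counts, informative_call("F1", "rs1", "ref"),
                              ped, snps)
  expect_equal(pc$mat_reads, 687L)
  expect_equal(pc$pat_reads, 35L)

  pc <- map_counts_to_parents(counts, informative_call("F1", "rs1", "alt"),
                              ped, snps)
  expect_equal(pc$mat_reads, 35L)
  expect_equal(pc$pat_reads, 687L)

  # pair with no pileup row: zero coverage, flagged
  pc <- map_counts_to_parents(counts[0, ], informative_call("F1", "rs1"),
                              ped, snps)
  expect_equal(pc$mat_reads, 0L)
  expect_true(pc$zero_coverage)

  bad <- informative_call("F1", "rs1")
  bad$status[1] <- "uninformative"
  expect_error(map_counts_to_parents(counts, bad, ped, snps), "informative")
})

test_that("coverage filter uses the median across informative placentas", {
  pc <- function(totals) tibble::tibble(
    family_id = paste0("F", seq_along(totals)), snp_id = "rs1",
    gene_id = "G1", mat_reads = as.integer(totals), pat_reads = 0L
  )
  expect_true(filter_snp_coverage(pc(c(3, 3, 3)))$pass)
  expect_false(filter_snp_coverage(pc(c(0, 1, 2)))$pass)
  expect_true(filter_snp_coverage(pc(c(0, 100, 100)))$pass)
})

test_that("gene aggregation sums families and SNPs", {
  pc <- tibble::tibble(
    family_id = c("F1", "F2", "F3", "F1", "F1"),
    snp_id = c("rs1", "rs1", "rs1", "rs2", "rs3"),
    gene_id = c(rep("G1", 3), "G2", "G2"),
    mat_reads = c(10L, 8L, 9L, 5L, 5L),
    pat_reads = c(0L, 1L, 0L, 5L, 5L)
  )
  agg <- aggregate_gene_counts(pc)
  g1 <- agg[agg$gene_id == "G1", ]
  expect_equal(c(g1$mat_total, g1$pat_total), c(27L, 1L))
  expect_equal(g1$n_informative_families, 3L)
  g2 <- agg[agg$gene_id == "G2", ]
  expect_equal(c(g2$mat_total, g2$pat_total), c(10L, 10L))
  expect_equal(aggregate_gene_counts(pc[0, ]) |> nrow(), 0L)
})

test_that("two-sided binomial p matches enumeration, closed forms and stats::binom.test", {
  expect_equal(binom_test_two_sided(10, 20), 1)
  expect_equal(binom_test_two_sided(0, 10), 2 * 2^-10)
  expect_equal(binom_test_two_sided(5, 29), 5.4611266e-4, tolerance = 1e-7)

  set.seed(7)
  for (n in sample(1:200, 40)) {
    k <- sample(0:n, 1)
    p <- binom_test_two_sided(k, n)
    expect_equal(p, oracle_binom_p(k, n), tolerance = 1e-10,
                 info = paste(k, n))
    expect_equal(p, stats::binom.test(k, n)$p.value, tolerance = 1e-10,
                 info = paste(k, n))
  }
  # asymmetric null keeps the R convention
  expect_equal(binom_test_two_sided(3, 10, 0.7),
               stats::binom.test(3, 10, 0.7)$p.value, tolerance = 1e-12)
  expect_error(binom_test_two_sided(1, 0), "n >= 1")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_adjust(1e-4, 91), 9.1e-3)
  expect_equal(bonferroni_adjust(0.5, 91), 1)
  p <- bonferroni_adjust(binom_test_two_sided(5, 29), 91)
  expect_lt(p, 0.05)
  expect_gt(p, 0.049)
})

test_that("proportion confidence intervals contain the estimate", {
  for (m in c("clopper_pearson", "wilson")) {
    ci <- proportion_ci(10, 10, method = m)
    expect_equal(unname(ci[["high"]]), 1)
    ci <- proportion_ci(687, 722, method = m)
    expect_true(ci[["low"]] <= 687 / 722 && 687 / 722 <= ci[["high"]])
  }
  ci <- proportion_ci(0, 10, method = "clopper_pearson")
  expect_equal(unname(ci[["low"]]), 0)
  expect_equal(unname(ci[["high"]]), 1 - 0.025^(1 / 10), tolerance = 1e-10)

  fam <- tibble::tibble(family_id = rep(paste0("F", 1:6), each = 1),
                        mat_reads = c(40L, 35L, 45L, 38L, 42L, 40L),
                        pat_reads = c(10L, 15L, 5L, 12L, 8L, 10L))
  k <- sum(fam$mat_reads); n <- sum(fam$mat_reads + fam$pat_reads)
  ci <- proportion_ci(k, n, method = "bootstrap", family_counts = fam,
                      n_boot = 500, seed = 1)
  expect_true(ci[["low"]] <= k / n && k / n <= ci[["high"]])
  ci2 <- proportion_ci(k, n, method = "bootstrap", family_counts = fam,
                       n_boot = 500, seed = 1)
  expect_identical(ci, ci2)
  expect_error(proportion_ci(1, 10, method = "bootstrap"), "family_counts")
})

test_that("classification follows the significance gate and fraction bands", {
  cfg <- poe_config(n_tests_bonferroni = 91)
  # strongly paternal gene: imprinted, Pat
  p <- bonferroni_adjust(binom_test_two_sided(13, 13 + 6101), 91)
  cl <- classify_gene(13 / (13 + 6101), p, cfg)
  expect_equal(as.character(cl$class), "imprinted")
  expect_equal(as.character(cl$expressed_parent), "Pat")
  # maternally skewed in the 65-90% band: biased, Mat
  p <- bonferroni_adjust(binom_test_two_sided(248, 331), 91)
  cl <- classify_gene(248 / 331, p, cfg)
  expect_equal(as.character(cl$class), "biased")
  expect_equal(as.character(cl$expressed_parent), "Mat")
  # balanced counts: biallelic regardless of n
  cl <- classify_gene(0.5, 1, cfg)
  expect_equal(as.character(cl$class), "biallelic")
  expect_equal(as.character(cl$expressed_parent), "both")
  # extreme fraction without significance stays biallelic
  cl <- classify_gene(0.95, 0.2, cfg)
  expect_equal(as.character(cl$class), "biallelic")
  # boundary: f = 0.90 goes to biased, just above to imprinted
  cl <- classify_gene(0.90, 1e-6, cfg)
  expect_equal(as.character(cl$class), "biased")
  cl <- classify_gene(0.901, 1e-6, cfg)
  expect_equal(as.character(cl$class), "imprinted")
})

test_that("gene summary pipeline classifies and partitions all genes", {
  pc <- tibble::tibble(
    family_id = rep(paste0("F", 1:4), 3),
    snp_id = rep(c("rs1", "rs2", "rs3"), each = 4),
    gene_id = rep(c("GM", "GB", "GN"), each = 4),
    clinical_group = factor(rep("PE", 12), levels = levels(tiny_pedigree()$clinical_group)),
    mat_reads = c(100L, 120L, 90L, 110L,   75L, 80L, 70L, 76L,  50L, 55L, 48L, 52L),
    pat_reads = c(1L, 0L, 2L, 1L,          25L, 20L, 30L, 24L,  50L, 52L, 49L, 50L)
  )
  s <- summarize_parental_expression(pc)
  expect_s3_class(s, "poe_summary")
  expect_equal(attr(s, "n_tests"), 3L)
  cls <- setNames(as.character(s$class), s$gene_id)
  expect_equal(cls[["GM"]], "imprinted")
  expect_equal(cls[["GB"]], "biased")
  expect_equal(cls[["GN"]], "biallelic")
  expect_true(all(s$ci_low <= s$mat_proportion & s$mat_proportion <= s$ci_high))
  expect_equal(s$p_corr, pmin(1, 3 * s$p_raw))

  # ref/alt label swap leaves the summary invariant when parental assignments
  # swap with it (mat/pat columns swap symmetric)
  pc_sw <- dplyr::mutate(pc, tmp = mat_reads, mat_reads = pat_reads,
                         pat_reads = tmp, tmp = NULL)
  s_sw <- summarize_parental_expression(pc_sw)
  j <- dplyr::inner_join(tibble::as_tibble(s), tibble::as_tibble(s_sw),
                         by = "gene_id", suffix = c("", ".sw"))
  expect_equal(j$mat_proportion, 1 - j$mat_proportion.sw)
  expect_equal(j$p_raw, j$p_raw.sw)
  expect_equal(as.character(j$class), as.character(j$class.sw))
})

test_that("underpowered and zero-coverage genes are excluded before testing, shrinking m", {
  pc <- tibble::tibble(
    family_id = c("F1", "F2", "F3", "F1", "F2", "F1", "F2", "F3"),
    snp_id = c(rep("rs1", 3), rep("rs2", 2), rep("rs3", 3)),
    gene_id = c(rep("G1", 3), rep("G2", 2), rep("G3", 3)),
    clinical_group = factor("PE", levels = levels(tiny_pedigree()$clinical_group)),
    mat_reads = c(10L, 12L, 9L, 8L, 9L, 0L, 0L, 0L),
    pat_reads = c(1L, 0L, 1L, 1L, 0L, 0L, 0L, 0L)
  )
  s <- summarize_parental_expression(pc)
  expect_equal(s$gene_id, "G1")
  expect_equal(attr(s, "n_tests"), 1L)
  excl <- attr(s, "excluded")
  expect_setequal(excl$gene_id, c("G2", "G3"))
})

test_that("class medians use the midpoint convention and split biased by parent", {
  s <- analyze_gene_totals(
    tibble::tibble(gene_id = c("A", "B", "C", "D"),
                   mat_total = c(990L, 830L, 200L, 170L),
                   pat_total = c(10L, 170L, 800L, 830L)),
    poe_config()
  )
  med <- class_medians(s)
  bi_pat <- med[med$class == "biased" & med$expressed_parent == "Pat", ]
  expect_equal(bi_pat$n_genes, 2L)
  expect_equal(bi_pat$median_preferred_fraction, (0.8 + 0.83) / 2)
  one <- med[med$class == "imprinted" & med$expressed_parent == "all", ]
  expect_equal(one$median_preferred_fraction, 0.99)
})

test_that("group breakdown conserves totals and marks empty groups", {
  pc <- tibble::tibble(
    family_id = c("F1", "F2", "F3"),
    snp_id = "rs1", gene_id = "G1",
    clinical_group = factor(c("PE", "PE", "trim1"),
                            levels = levels(tiny_pedigree()$clinical_group)),
    mat_reads = c(30L, 20L, 10L), pat_reads = c(3L, 2L, 1L)
  )
  bd <- group_breakdown(pc)
  expect_equal(nrow(bd), 7L)  # one row per clinical group
  expect_equal(sum(bd$mat_reads), 60L)
  expect_equal(sum(bd$pat_reads), 6L)
  pe <- bd[bd$clinical_group == "PE", ]
  expect_equal(pe$mat_proportion, 50 / 55)
  empty <- bd[bd$clinical_group == "GD", ]
  expect_true(is.na(empty$mat_proportion))
  expect_equal(empty$mat_reads, 0L)

  # all families in one group: breakdown equals the overall summary
  pc1 <- dplyr::mutate(pc, clinical_group = factor("PE", levels = levels(clinical_group)))
  bd1 <- group_breakdown(pc1)
  expect_equal(bd1$mat_proportion[bd1$clinical_group == "PE"], 60 / 66)
})
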
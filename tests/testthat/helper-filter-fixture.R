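# Deterministic 50-gene fixture for filter-bookkeeping checks: 26 clean genes
# plus planted failures at every stage. Genotype patterns are constructed in
# exact Hardy-Weinberg proportions (no sampling), so the only HWE violations
# are the planted ones.

filter_fixture_genes <- function() {
  list(
    control = sprintf("CTRL%02d", 1:26),
    low_expr = sprintf("LOWEXPR%d", 1:5),
    unannotated = sprintf("UNANN%d", 1:3),
    low_maf = sprintf("LOWMAF%d", 1:4),
    hwe_violation = sprintf("HWEV%d", 1:4),
    under_informative = sprintf("UNDERINF%d", 1:4),
    low_coverage = sprintf("LOWCOV%d", 1:4)
  )
}

build_filter_fixture <- function() {
  fams <- cohort_layout()
  fams$placenta <- paste0(fams$family_id, "_PL")
  fams$mother <- paste0(fams$family_id, "_M")
  fams$father <- ifelse(fams$has_father, paste0(fams$family_id, "_F"),
                        NA_character_)
  ped <- tibble::tibble(
    family_id = fams$family_id, placenta = fams$placenta,
    mother = fams$mother, father = fams$father,
    clinical_group = fams$clinical_group,
    gestational_age_days = fams$gestational_age_days
  )
  n_fam <- nrow(fams)
  block <- (seq_len(n_fam) - 1L) %% 4L

  # exact-HWE pattern with informative families in blocks 0 and 1
  informative_pattern <- data.frame(
    mother = c("hom_ref", "hom_alt", "het", "het"),
    father = c("hom_alt", "hom_ref", "het", "het"),
    placenta = c("het", "het", "hom_ref", "hom_alt")
  )[block + 1L, ]
  # exact-HWE pattern with no informative family at all
  uninformative_pattern <- data.frame(
    mother = c("het", "hom_ref", "hom_alt", "het"),
    father = c("het", "hom_ref", "hom_alt", "het"),
    placenta = c("het", "hom_ref", "hom_alt", "het")
  )[block + 1L, ]
  # two informative families only (families 1 and 2), rest undecidable
  under_informative_pattern <- uninformative_pattern
  under_informative_pattern[1, ] <- c("hom_ref", "hom_alt", "het")
  under_informative_pattern[2, ] <- c("hom_alt", "hom_ref", "het")
  # one carrier among the mothers: cohort MAF far below 10%
  low_maf_pattern <- data.frame(
    mother = c("het", rep("hom_ref", n_fam - 1L)),
    father = rep("hom_ref", n_fam), placenta = rep("hom_ref", n_fam)
  )
  # heterozygote void: half hom_ref, half hom_alt families
  hwe_pattern <- data.frame(
    mother = ifelse(block < 2L, "hom_ref", "hom_alt"),
    father = ifelse(block < 2L, "hom_ref", "hom_alt"),
    placenta = ifelse(block < 2L, "hom_ref", "hom_alt")
  )

  genes <- filter_fixture_genes()
  pattern_of <- function(gene) {
    if (gene %in% genes$low_maf) low_maf_pattern
    else if (gene %in% genes$hwe_violation) hwe_pattern
    else if (gene %in% genes$under_informative) under_informative_pattern
    else informative_pattern
  }

  all_genes <- unlist(genes, use.names = FALSE)
  gt_rows <- list()
  count_rows <- list()
  sites <- list()
  exon_rows <- list()
  for (gi in seq_along(all_genes)) {
    gene <- all_genes[gi]
    snp <- paste0("snp_", gene)
    pos <- 1000L * gi
    sites[[gi]] <- tibble::tibble(snp_id = snp, chrom = "chr1", pos = pos,
                                  ref = "A", alt = "G")
    if (!gene %in% genes$unannotated) {
      exon_rows[[gi]] <- tibble::tibble(chrom = "chr1", start = pos - 10L,
                                        end = pos + 10L, gene_id = gene)
    }
    pat <- pattern_of(gene)
    gt_rows[[gi]] <- tibble::tibble(
      sample = c(fams$placenta, fams$mother, fams$father[fams$has_father]),
      snp_id = snp,
      genotype = c(pat$placenta, pat$mother, pat$father[fams$has_father])
    )
    depth <- if (gene %in% genes$low_coverage) c(1L, 0L) else c(25L, 15L)
    count_rows[[gi]] <- tibble::tibble(
      sample = fams$placenta, snp_id = snp,
      ref_count = ifelse(pat$placenta == "hom_alt", depth[2], depth[1]),
      alt_count = ifelse(pat$placenta == "hom_ref", 0L,
                         ifelse(pat$placenta == "hom_alt", depth[1], depth[2]))
    )
  }
  genotypes <- dplyr::bind_rows(gt_rows)
  genotypes$genotype <- factor(genotypes$genotype,
                               levels = c("hom_ref", "het", "hom_alt", "missing"))
  attr(genotypes, "sites") <- dplyr::bind_rows(sites)

  expr_level <- ifelse(all_genes %in% genes$low_expr, 2L, 500L)
  gene_counts <- dplyr::bind_cols(
    tibble::tibble(gene_id = all_genes),
    tibble::as_tibble(matrix(rep(expr_level, n_fam), ncol = n_fam,
                             dimnames = list(NULL, fams$placenta)))
  )

  list(
    genotypes = genotypes, pedigree = ped,
    allelic_counts = dplyr::bind_rows(count_rows),
    gene_counts = gene_counts,
    exons = dplyr::bind_rows(exon_rows),
    genes = genes
  )
}
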
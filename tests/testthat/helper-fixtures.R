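# Shared fixtures and independent oracles.

# Brute-force parental-origin oracle: enumerate every Mendelian-consistent
# (maternal, paternal) transmission; informative iff the placenta is het and
# exactly one assignment is consistent. Independent of the decision table.
oracle_classify <- function(placenta, mother, father = NA) {
  alleles_of <- function(gt) switch(gt,
    hom_ref = c("ref", "ref"), het = c("ref", "alt"), hom_alt = c("alt", "alt"))
  if (placenta != "het") {
    # non-het placentas are uninformative by definition (no allelic contrast)
    return(list(status = "uninformative", maternal = NA_character_,
                paternal = NA_character_))
  }
  m_all <- unique(alleles_of(mother))
  f_all <- if (is.na(father)) c("ref", "alt") else unique(alleles_of(father))
  target <- c("ref", "alt")
  consistent <- list()
  for (m in m_all) for (f in f_all) {
    if (setequal(c(m, f), target)) consistent <- c(consistent, list(c(m, f)))
  }
  consistent <- unique(consistent)
  if (length(consistent) == 0L) {
    list(status = "mendelian_error", maternal = NA_character_,
         paternal = NA_character_)
  } else if (length(consistent) == 1L) {
    list(status = "informative", maternal = consistent[[1]][1],
         paternal = consistent[[1]][2])
  } else {
    list(status = "uninformative", maternal = NA_character_,
         paternal = NA_character_)
  }
}

# Brute-force two-sided binomial p: enumerate the full pmf and sum every
# outcome whose point probability is <= the observed one.
oracle_binom_p <- function(k, n, p0 = 0.5) {
  probs <- dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}

# Minimal three-family pedigree: two trios and one duo.
tiny_pedigree <- function() {
  tibble::tibble(
    family_id = c("F1", "F2", "F3"),
    placenta = c("P1", "P2", "P3"),
    mother = c("M1", "M2", "M3"),
    father = c("D1", "D2", NA),
    clinical_group = factor(c("PE", "trim1", "trim3_normal"),
                            levels = c("trim1", "trim2", "trim3_normal",
                                       "SGA", "LGA", "PE", "GD")),
    gestational_age_days = c(268L, 60L, 280L)
  )
}

# Genotype table (with sites attribute) from a long data frame.
tiny_genotypes <- function(df, sites = NULL) {
  gt <- tibble::as_tibble(df)
  gt$genotype <- factor(gt$genotype,
                        levels = c("hom_ref", "het", "hom_alt", "missing"))
  if (is.null(sites)) {
    ids <- unique(gt$snp_id)
    sites <- tibble::tibble(snp_id = ids, chrom = "chr1",
                            pos = seq(150L, by = 100L, length.out = length(ids)),
                            ref = "A", alt = "G")
  }
  attr(gt, "sites") <- sites
  gt
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
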
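#' Analysis configuration
#'
#' Bundles every tunable threshold of the parent-of-origin expression pipeline
#' in one validated object. Defaults follow the stringent candidate-imprinted
#' gene screen they were designed for: genes need a median normalized
#' expression of at least 50 reads, marker SNPs a cohort minor allele frequency
#' above 10%, Hardy-Weinberg equilibrium (chi-square p > 0.05), at least 3
#' informative trios/duos, and a median read coverage of at least 3 across
#' informative placentas. Classification calls a gene imprinted when more than
#' 90% of reads come from one parental allele (with Bonferroni-corrected
#' binomial p < alpha), parentally biased between 65% and 90%, and biallelic
#' otherwise.
#'
#' @param n_tests_bonferroni Bonferroni divisor. `NULL` (default) uses the
#'   number of genes reaching the testing stage in the current run; set an
#'   integer to fix the divisor (e.g. to compare against an external screen
#'   that tested a known number of genes).
#' @param min_informative_families Minimum informative trios/duos per SNP.
#' @param min_median_reads Minimum median read coverage at a SNP across its
#'   informative placentas.
#' @param maf_threshold Minor allele frequency threshold; SNPs pass with
#'   MAF strictly greater than this.
#' @param hwe_alpha Hardy-Weinberg chi-square significance level; SNPs pass
#'   with p strictly greater than this.
#' @param expression_median_threshold Minimum median normalized read count for
#'   a gene to be considered expressed.
#' @param imprinted_threshold Preferred-allele fraction above which a
#'   significant gene is called imprinted (strictly greater).
#' @param biased_low Lower bound of the preferred-allele fraction for the
#'   biased class (inclusive).
#' @param biallelic_band Length-2 numeric; maternal proportions inside this
#'   band describe biallelic expression (reporting only; the classifier uses
#'   `biased_low` / `imprinted_threshold`).
#' @param alpha Significance level applied to the Bonferroni-corrected p.
#' @param ci_method Confidence-interval method for the maternal read
#'   proportion: `"clopper_pearson"` (default), `"wilson"`, or `"bootstrap"`
#'   (percentile interval resampling whole families).
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param snp_exclusion_list Character vector of SNP ids to drop from the
#'   analysis (stand-in for manual curation of SNPs in alternative exons
#'   overlapping introns of the main transcript).
#' @param trio_het_mother_informative Logical; when `TRUE` (default) a trio
#'   with heterozygous (or missing) mother and homozygous father is
#'   informative — "at least one homozygous parent" — rather than requiring a
#'   homozygous mother.
#'
#' @return A list with class `"poe_config"`.
#' @examples
#' cfg <- poe_config(n_tests_bonferroni = 91)
#' cfg$imprinted_threshold
#' @export
poe_config <- function(n_tests_bonferroni = NULL,
                       min_informative_families = 3L,
                       min_median_reads = 3,
                       maf_threshold = 0.10,
                       hwe_alpha = 0.05,
                       expression_median_threshold = 50,
                       imprinted_threshold = 0.90,
                       biased_low = 0.65,
                       biallelic_band = c(0.35, 0.65),
                       alpha = 0.05,
                       ci_method = c("clopper_pearson", "wilson", "bootstrap"),
                       n_boot = 2000L,
                       snp_exclusion_list = character(),
                       trio_het_mother_informative = TRUE) {
  ci_method <- match.arg(ci_method)
  cfg <- list(
    n_tests_bonferroni = n_tests_bonferroni,
    min_informative_families = as.integer(min_informative_families),
    min_median_reads = min_median_reads,
    maf_threshold = maf_threshold,
    hwe_alpha = hwe_alpha,
    expression_median_threshold = expression_median_threshold,
    imprinted_threshold = imprinted_threshold,
    biased_low = biased_low,
    biallelic_band = biallelic_band,
    alpha = alpha,
    ci_method = ci_method,
    n_boot = as.integer(n_boot),
    snp_exclusion_list = as.character(snp_exclusion_list),
    trio_het_mother_informative = isTRUE(trio_het_mother_informative)
  )
  validate_poe_config(cfg)
  structure(cfg, class = "poe_config")
}

validate_poe_config <- function(cfg) {
  frac <- c(
    maf_threshold = cfg$maf_threshold, hwe_alpha = cfg$hwe_alpha,
    imprinted_threshold = cfg$imprinted_threshold, biased_low = cfg$biased_low,
    alpha = cfg$alpha
  )
  bad <- frac <= 0 | frac >= 1
  if (any(bad)) {
    abort(paste0("poe_config: fractions must lie in (0, 1): ",
                 paste(names(frac)[bad], collapse = ", ")))
  }
  if (length(cfg$biallelic_band) != 2L ||
      !(0 < cfg$biallelic_band[1] && cfg$biallelic_band[1] < cfg$biallelic_band[2] &&
        cfg$biallelic_band[2] < 1)) {
    abort("poe_config: biallelic_band must be two increasing fractions in (0, 1)")
  }
  if (!(cfg$biallelic_band[1] < cfg$biased_low &&
        cfg$biased_low <= cfg$imprinted_threshold)) {
    abort("poe_config: need biallelic_band[1] < biased_low <= imprinted_threshold")
  }
  ints <- c(min_informative_families = cfg$min_informative_families,
            min_median_reads = cfg$min_median_reads,
            expression_median_threshold = cfg$expression_median_threshold)
  if (any(ints < 0)) {
    abort("poe_config: integer thresholds must be >= 0")
  }
  if (!is.null(cfg$n_tests_bonferroni) &&
      (length(cfg$n_tests_bonferroni) != 1L || cfg$n_tests_bonferroni < 1)) {
    abort("poe_config: n_tests_bonferroni must be a positive scalar or NULL")
  }
  invisible(cfg)
}

#' @export
print.poe_config <- function(x, ...) {
  cat("<poe_config>\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ", "), character(1))
  flat[lengths(x) == 0L] <- "<empty>"
  flat["n_tests_bonferroni"] <- if (is.null(x$n_tests_bonferroni)) {
    "<number of tested genes>"
  } else {
    format(x$n_tests_bonferroni)
  }
  cat(sprintf("  %-28s %s\n", names(flat), flat), sep = "")
  invisible(x)
}

as_poe_config <- function(config) {
  if (inherits(config, "poe_config")) return(config)
  if (is.null(config)) return(poe_config())
  abort("`config` must be created by poe_config()")
}
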
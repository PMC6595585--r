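#' Map allelic read tallies to parental read counts
#'
#' For each informative (family, SNP) call, relabels the placenta's ref/alt
#' read tallies as maternal/paternal according to the call's allele
#' assignment. Calls that are not informative are refused: filter first.
#'
#' @param allelic_counts Tibble from [read_allelic_counts()].
#' @param calls Informative rows of [call_parental_origin()].
#' @param pedigree Pedigree tibble (links families to placenta samples).
#' @param snps SNP table carrying `snp_id` and `gene_id` (e.g. the `snps`
#'   element of [filter_candidates()]).
#' @return Tibble with columns `family_id`, `snp_id`, `gene_id`,
#'   `clinical_group`, `mat_reads`, `pat_reads`, `zero_coverage`. Pairs with
#'   no row in `allelic_counts` get zero reads.
#' @export
map_counts_to_parents <- function(allelic_counts, calls, pedigree, snps) {
  if (any(calls$status != "informative")) {
    abort("map_counts_to_parents expects informative calls only; filter first")
  }
  calls |>
    left_join(pedigree |> select("family_id", "placenta", "clinical_group"),
              by = "family_id") |>
    left_join(allelic_counts, by = c(placenta = "sample", "snp_id")) |>
    inner_join(snps |> select("snp_id", "gene_id"), by = "snp_id") |>
    mutate(
      ref_count = ifelse(is.na(.data$ref_count), 0L, .data$ref_count),
      alt_count = ifelse(is.na(.data$alt_count), 0L, .data$alt_count),
      mat_reads = ifelse(.data$maternal_allele == "ref", .data$ref_count,
                         .data$alt_count),
      pat_reads = ifelse(.data$paternal_allele == "ref", .data$ref_count,
                         .data$alt_count),
      zero_coverage = .data$mat_reads + .data$pat_reads == 0L
    ) |>
    select("family_id", "snp_id", "gene_id", "clinical_group", "mat_reads",
           "pat_reads", "zero_coverage")
}

#' Read-coverage filter per SNP
#'
#' A SNP passes when the median total read count (maternal + paternal) across
#' its informative placentas is at least `min_median_reads`; only medians
#' strictly below the threshold drop the SNP.
#'
#' @param parental_counts Tibble from [map_counts_to_parents()].
#' @param config A [poe_config()].
#' @return Tibble with columns `snp_id`, `median_reads`, `pass`.
#' @export
filter_snp_coverage <- function(parental_counts, config = poe_config()) {
  config <- as_poe_config(config)
  parental_counts |>
    group_by(.data$snp_id) |>
    summarise(median_reads = median(.data$mat_reads + .data$pat_reads),
              .groups = "drop") |>
    mutate(pass = .data$median_reads >= config$min_median_reads)
}

#' Aggregate parental read counts to the gene level
#'
#' Simple sums of maternal and paternal reads over every informative
#' (family, SNP) pair of the gene. Reads are summed across a gene's multiple
#' SNPs within a sample; a fragment overlapping two SNPs is therefore counted
#' at both, matching the upstream per-SNP pileup convention.
#'
#' @param parental_counts Tibble from [map_counts_to_parents()] (after SNP
#'   coverage filtering).
#' @return Tibble with columns `gene_id`, `mat_total`, `pat_total`,
#'   `n_informative_families`, `n_snps`.
#' @export
aggregate_gene_counts <- function(parental_counts) {
  parental_counts |>
    group_by(.data$gene_id) |>
    summarise(
      mat_total = sum(.data$mat_reads),
      pat_total = sum(.data$pat_reads),
      n_informative_families = n_distinct(.data$family_id),
      n_snps = n_distinct(.data$snp_id),
      .groups = "drop"
    )
}

#' Exact two-sided binomial test
#'
#' Two-sided p-value against `Binomial(n, p0)` computed by the sum-of-small
#' point probabilities convention: every outcome whose point probability does
#' not exceed that of the observed count (within relative tolerance 1e-7)
#' contributes. For `p0 = 0.5` this equals `min(1, 2 * smaller tail)`.
#' Vectorised over `k` and `n`.
#'
#' @param k Observed successes.
#' @param n Number of trials (>= 1).
#' @param p0 Null success probability.
#' @return P-value(s) in \[0, 1\].
#' @examples
#' binom_test_two_sided(5, 29) # 5.461e-4
#' @export
binom_test_two_sided <- function(k, n, p0 = 0.5) {
  if (any(n < 1)) abort("binomial test needs n >= 1")
  if (any(k < 0 | k > n)) abort("need 0 <= k <= n")
  mapply(function(k1, n1) {
    d <- dbinom(k1, n1, p0)
    probs <- dbinom(0:n1, n1, p0)
    min(1, sum(probs[probs <= d * (1 + 1e-7)]))
  }, k, n)
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value(s).
#' @param m Number of tests.
#' @return `min(1, m * p_raw)`, vectorised.
#' @export
bonferroni_adjust <- function(p_raw, m) {
  if (m < 1) abort("Bonferroni divisor m must be >= 1")
  pmin(1, m * p_raw)
}

#' Confidence interval for a binomial proportion
#'
#' Clopper-Pearson (exact beta-quantile), Wilson (score), or a percentile
#' bootstrap that resamples whole families — the sampling unit of the cohort
#' — and recomputes the pooled proportion. All methods return an interval
#' containing the point estimate `k/n`.
#'
#' @param k,n Successes and trials.
#' @param method `"clopper_pearson"`, `"wilson"`, or `"bootstrap"`.
#' @param alpha Two-sided error rate (default 0.05 for a 95% interval).
#' @param family_counts For the bootstrap: tibble with columns `mat_reads`,
#'   `pat_reads`, one row per (family, SNP) observation, plus `family_id`.
#' @param n_boot Bootstrap replicates.
#' @param seed Optional seed for the bootstrap.
#' @return Named numeric vector `c(low, high)`.
#' @export
proportion_ci <- function(k, n, method = c("clopper_pearson", "wilson",
                                           "bootstrap"),
                          alpha = 0.05, family_counts = NULL,
                          n_boot = 2000L, seed = NULL) {
  method <- match.arg(method)
  if (n < 1) abort("proportion_ci needs n >= 1")
  est <- k / n
  ci <- switch(method,
    clopper_pearson = c(
      low = if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1),
      high = if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
    ),
    wilson = {
      z <- qnorm(1 - alpha / 2)
      centre <- (est + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z / (1 + z^2 / n) * sqrt(est * (1 - est) / n + z^2 / (4 * n^2))
      c(low = max(0, centre - half), high = min(1, centre + half))
    },
    bootstrap = {
      if (is.null(family_counts)) {
        abort("bootstrap CI needs per-family counts (family_counts)")
      }
      if (!is.null(seed)) withr::local_seed(seed)
      fam <- family_counts |>
        group_by(.data$family_id) |>
        summarise(mat = sum(.data$mat_reads), tot = sum(.data$mat_reads + .data$pat_reads),
                  .groups = "drop")
      nf <- nrow(fam)
      props <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(nf, nf, replace = TRUE)
        tot <- sum(fam$tot[idx])
        if (tot == 0) est else sum(fam$mat[idx]) / tot
      }, numeric(1))
      q <- unname(stats::quantile(props, c(alpha / 2, 1 - alpha / 2)))
      c(low = min(q[1], est), high = max(q[2], est))
    }
  )
  ci
}

#' Classify a gene's parental expression pattern
#'
#' Let `f` be the preferred-allele fraction `max(p, 1 - p)` of the maternal
#' read proportion `p`, and `p_corr` the Bonferroni-corrected binomial
#' p-value. A gene is `imprinted` when `p_corr < alpha` and `f` strictly
#' exceeds the imprinted threshold (0.90), `biased` when `p_corr < alpha`
#' and `f` lies in \[0.65, 0.90\], and `biallelic` otherwise (no significant
#' deviation, or parental proportions within the 35–65% band). The expressed
#' parent is `Mat`/`Pat` by the direction of the skew, `both` for biallelic
#' genes.
#'
#' @param mat_proportion Maternal read proportion(s).
#' @param p_corr Bonferroni-corrected p-value(s).
#' @param config A [poe_config()].
#' @return Tibble with columns `class` (factor imprinted/biased/biallelic)
#'   and `expressed_parent` (factor Mat/Pat/both).
#' @export
classify_gene <- function(mat_proportion, p_corr, config = poe_config()) {
  config <- as_poe_config(config)
  f <- pmax(mat_proportion, 1 - mat_proportion)
  sig <- p_corr < config$alpha
  class <- case_when(
    sig & f > config$imprinted_threshold ~ "imprinted",
    sig & f >= config$biased_low ~ "biased",
    TRUE ~ "biallelic"
  )
  parent <- case_when(
    class == "biallelic" ~ "both",
    mat_proportion > 0.5 ~ "Mat",
    TRUE ~ "Pat"
  )
  tibble(class = factor(class, levels = POE_CLASSES),
         expressed_parent = factor(parent, levels = c("Mat", "Pat", "both")))
}

#' Gene-level parental expression summary
#'
#' The pipeline's central computation: starting from per-(family, SNP)
#' parental read counts, applies the SNP-level informative-family and read
#' coverage filters, sums maternal and paternal reads per gene, tests the
#' pooled maternal proportion against 0.5 with the exact binomial test,
#' applies Bonferroni correction over the genes actually tested (or a fixed
#' divisor from the config), attaches a confidence interval, and classifies
#' every gene as imprinted, parentally biased, or biallelic.
#'
#' @param parental_counts Tibble from [map_counts_to_parents()].
#' @param config A [poe_config()].
#' @return A tibble of class `"poe_summary"`, one row per tested gene:
#'   `gene_id`, `mat_total`, `pat_total`, `mat_proportion`, `ci_low`,
#'   `ci_high`, `p_raw`, `p_corr`, `preferred_fraction`, `class`,
#'   `expressed_parent`, `n_informative_families`, `n_snps`. Attributes:
#'   `n_tests` (the Bonferroni divisor), `config`, `excluded` (genes dropped
#'   before testing, with reasons), `snp_coverage` (the per-SNP filter table).
#' @export
summarize_parental_expression <- function(parental_counts,
                                          config = poe_config()) {
  config <- as_poe_config(config)

  per_snp <- parental_counts |>
    group_by(.data$snp_id) |>
    summarise(n_informative = n_distinct(.data$family_id),
              median_reads = median(.data$mat_reads + .data$pat_reads),
              .groups = "drop") |>
    mutate(informative_pass = .data$n_informative >= config$min_informative_families,
           coverage_pass = .data$median_reads >= config$min_median_reads)
  good_snps <- per_snp$snp_id[per_snp$informative_pass & per_snp$coverage_pass]

  kept <- parental_counts |> filter(.data$snp_id %in% good_snps)
  agg <- aggregate_gene_counts(kept)

  excluded <- bind_rows(
    parental_counts |>
      distinct(.data$gene_id) |>
      anti_join(agg, by = "gene_id") |>
      mutate(reason = "no_passing_snp"),
    agg |>
      filter(.data$n_informative_families < config$min_informative_families |
               .data$mat_total + .data$pat_total == 0L) |>
      transmute(.data$gene_id,
                reason = as.character(
                  ifelse(.data$mat_total + .data$pat_total == 0L,
                         "zero_reads", "too_few_informative_families")))
  )
  tested <- agg |> anti_join(excluded, by = "gene_id")

  build_gene_summary(tested, config,
                     family_counts = kept |> filter(.data$gene_id %in% tested$gene_id),
                     excluded = excluded, snp_coverage = per_snp)
}

#' Summarize genes from pre-aggregated maternal/paternal totals
#'
#' Entry point for re-analysing published gene-level read counts: takes
#' maternal and paternal totals directly (skipping the per-SNP stages) and
#' runs the same test-correct-classify chain as
#' [summarize_parental_expression()].
#'
#' @param gene_totals Tibble with columns `gene_id`, `mat_total`,
#'   `pat_total`.
#' @param config A [poe_config()]; set `n_tests_bonferroni` to reproduce a
#'   screen that tested more genes than are being re-analysed.
#' @return A `"poe_summary"` tibble (see [summarize_parental_expression()]).
#' @examples
#' analyze_gene_totals(
#'   poe_reference_counts(),
#'   config = poe_config(n_tests_bonferroni = 91)
#' )
#' @export
analyze_gene_totals <- function(gene_totals, config = poe_config()) {
  config <- as_poe_config(config)
  tested <- gene_totals |>
    mutate(n_informative_families = NA_integer_, n_snps = NA_integer_) |>
    filter(.data$mat_total + .data$pat_total > 0L)
  build_gene_summary(tested, config)
}

build_gene_summary <- function(tested, config, family_counts = NULL,
                               excluded = tibble(gene_id = character(),
                                                 reason = character()),
                               snp_coverage = NULL) {
  m <- config$n_tests_bonferroni %||% nrow(tested)
  out <- tested |>
    mutate(
      mat_proportion = .data$mat_total / (.data$mat_total + .data$pat_total),
      p_raw = binom_test_two_sided(.data$mat_total,
                                   .data$mat_total + .data$pat_total),
      p_corr = bonferroni_adjust(.data$p_raw, m),
      preferred_fraction = pmax(.data$mat_proportion, 1 - .data$mat_proportion)
    )
  ci_tbl <- purrr::pmap_dfr(
    list(out$gene_id, out$mat_total, out$mat_total + out$pat_total),
    function(g, k, n) {
      fam <- if (!is.null(family_counts) && config$ci_method == "bootstrap") {
        family_counts |> filter(.data$gene_id == g)
      } else NULL
      ci <- proportion_ci(k, n, method = config$ci_method,
                          alpha = config$alpha, family_counts = fam,
                          n_boot = config$n_boot)
      tibble(ci_low = ci[["low"]], ci_high = ci[["high"]])
    }
  )
  out <- bind_cols(out, ci_tbl)
  out <- bind_cols(out, classify_gene(out$mat_proportion, out$p_corr, config)) |>
    select("gene_id", "mat_total", "pat_total", "mat_proportion", "ci_low",
           "ci_high", "p_raw", "p_corr", "preferred_fraction", "class",
           "expressed_parent", "n_informative_families", "n_snps") |>
    arrange(.data$class, desc(.data$preferred_fraction))
  structure(out, class = c("poe_summary", class(out)),
            n_tests = m, config = config, excluded = excluded,
            snp_coverage = snp_coverage)
}

#' Per-class medians of the preferred-allele fraction
#'
#' Medians (midpoint convention for even counts) of the preferred-allele
#' fraction, overall per class and — for the biased class — split by the
#' expressed parent. Empty classes are omitted.
#'
#' @param summary A `"poe_summary"` tibble.
#' @return Tibble with columns `class`, `expressed_parent` (`"all"` for the
#'   whole-class rows), `n_genes`, `median_preferred_fraction`.
#' @export
class_medians <- function(summary) {
  overall <- summary |>
    group_by(.data$class) |>
    summarise(expressed_parent = "all", n_genes = n(),
              median_preferred_fraction = median(.data$preferred_fraction),
              .groups = "drop")
  split <- summary |>
    filter(.data$class == "biased") |>
    group_by(.data$class, expressed_parent = as.character(.data$expressed_parent)) |>
    summarise(n_genes = n(),
              median_preferred_fraction = median(.data$preferred_fraction),
              .groups = "drop")
  bind_rows(overall, split) |>
    arrange(.data$class, .data$expressed_parent != "all", .data$expressed_parent)
}

#' Per-clinical-group parental read breakdown
#'
#' Re-runs the gene-level aggregation restricted to each clinical subgroup.
#' Groups with no informative reads for a gene are reported with `NA`
#' proportion (empty, not zero). Summing the per-group maternal/paternal
#' totals over groups recovers the overall totals.
#'
#' @param parental_counts Tibble from [map_counts_to_parents()] (restricted
#'   to the SNPs that passed filtering, e.g. via the `snp_coverage` attribute
#'   of the summary).
#' @param config A [poe_config()].
#' @return Tibble with one row per gene and clinical group: `gene_id`,
#'   `clinical_group`, `mat_reads`, `pat_reads`, `mat_proportion`, `ci_low`,
#'   `ci_high`, `n_families`.
#' @export
group_breakdown <- function(parental_counts, config = poe_config()) {
  config <- as_poe_config(config)
  full <- tidyr::expand_grid(
    gene_id = unique(parental_counts$gene_id),
    clinical_group = factor(POE_GROUPS, levels = POE_GROUPS)
  )
  by_group <- parental_counts |>
    group_by(.data$gene_id, .data$clinical_group) |>
    summarise(mat_reads = sum(.data$mat_reads), pat_reads = sum(.data$pat_reads),
              n_families = n_distinct(.data$family_id), .groups = "drop")
  full |>
    left_join(by_group, by = c("gene_id", "clinical_group")) |>
    mutate(
      mat_reads = ifelse(is.na(.data$mat_reads), 0L, .data$mat_reads),
      pat_reads = ifelse(is.na(.data$pat_reads), 0L, .data$pat_reads),
      n_families = ifelse(is.na(.data$n_families), 0L, .data$n_families),
      total = .data$mat_reads + .data$pat_reads,
      mat_proportion = ifelse(.data$total > 0, .data$mat_reads / .data$total,
                              NA_real_)
    ) |>
    rowwise() |>
    mutate(
      ci_low = if (.data$total > 0) {
        proportion_ci(.data$mat_reads, .data$total,
                      method = if (identical(config$ci_method, "bootstrap"))
                        "clopper_pearson" else config$ci_method,
                      alpha = config$alpha)[["low"]]
      } else NA_real_,
      ci_high = if (.data$total > 0) {
        proportion_ci(.data$mat_reads, .data$total,
                      method = if (identical(config$ci_method, "bootstrap"))
                        "clopper_pearson" else config$ci_method,
                      alpha = config$alpha)[["high"]]
      } else NA_real_
    ) |>
    ungroup() |>
    select("gene_id", "clinical_group", "mat_reads", "pat_reads",
           "mat_proportion", "ci_low", "ci_high", "n_families")
}

#' Published placental parental read counts (25-gene reference panel)
#'
#' Maternal and paternal RNA-seq read totals for the 25 genes reported with
#' parent-of-origin-driven allelic expression in a published screen of 91
#' candidate imprinted genes in human placenta (11 imprinted and 14
#' parentally biased loci, e.g. MEG3, H19, PEG10, IGF2, KLHDC10, RHOBTB3).
#' Useful as a worked example and as a fixture: re-analysing these totals
#' with `poe_config(n_tests_bonferroni = 91)` reproduces the published
#' proportions and class labels.
#'
#' @return Tibble with columns `gene_id`, `mat_total`, `pat_total`.
#' @examples
#' head(poe_reference_counts())
#' @export
poe_reference_counts <- function() {
  path <- system.file("extdata", "placenta_reference_counts.tsv",
                      package = "imprintr", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cii")
}
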
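#' Run the full parent-of-origin expression pipeline
#'
#' Chains every stage on in-memory tables: candidate gene/SNP filtering
#' (annotation, expression, MAF, Hardy-Weinberg, exonic location), parental
#' origin calling over trios/duos, the informative-family and read-coverage
#' SNP filters, gene-level aggregation with exact binomial testing and
#' Bonferroni correction, three-way classification, and the per-clinical-group
#' breakdown. The filter trace records, stage by stage, how many genes
#' survived and why each dropped gene fell out; gene sets are nested across
#' stages and dropouts plus survivors always sum to the candidate count.
#'
#' @param genotypes Genotype tibble from [read_genotypes()] or a
#'   [sim_cohort()] element.
#' @param pedigree Pedigree tibble from [read_pedigree()].
#' @param allelic_counts Allelic count tibble from [read_allelic_counts()].
#' @param gene_counts Gene count tibble from [read_gene_counts()] (defines
#'   the candidate gene panel).
#' @param exons Exon tibble from [read_exon_bed()].
#' @param config A [poe_config()].
#' @return A list of class `"poe_result"`: `summary` (the `"poe_summary"`
#'   tibble), `breakdown` (per-group), `trace` (the filter trace), `snps`
#'   (retained SNP records), `calls` (all parental-origin calls),
#'   `parental_counts` (per family/SNP maternal/paternal reads on retained
#'   SNPs), and `config`.
#' @examples
#' cohort <- sim_cohort(sim_gene_models(n_snps = 1, mean_depth = 40), seed = 7)
#' res <- poe_pipeline(cohort$genotypes, cohort$pedigree,
#'                     cohort$allelic_counts, cohort$gene_counts,
#'                     cohort$exons)
#' glance(res$summary)
#' @export
poe_pipeline <- function(genotypes, pedigree, allelic_counts, gene_counts,
                         exons, config = poe_config()) {
  config <- as_poe_config(config)

  filt <- filter_candidates(genotypes, gene_counts, exons, config)
  trace <- filt$trace
  snps <- filt$snps

  calls <- call_parental_origin(genotypes, pedigree,
                                snp_ids = snps$snp_id, config = config)
  inf <- count_informative_families(calls, config)
  snps_inf <- snps |> filter(.data$snp_id %in% inf$snp_id[inf$pass])
  trace <- add_filter_stage(trace, "informative_families",
                            intersect(trace$retained, unique(snps_inf$gene_id)),
                            "too_few_informative_families")

  informative <- calls |>
    filter(.data$status == "informative",
           .data$snp_id %in% snps_inf$snp_id)
  parental <- map_counts_to_parents(allelic_counts, informative, pedigree,
                                    snps_inf)
  cov <- filter_snp_coverage(parental, config)
  parental_kept <- parental |> filter(.data$snp_id %in% cov$snp_id[cov$pass])
  trace <- add_filter_stage(trace, "read_coverage",
                            intersect(trace$retained,
                                      unique(parental_kept$gene_id)),
                            "low_read_coverage")

  summary <- summarize_parental_expression(parental_kept, config)
  excluded <- attr(summary, "excluded")
  reasons <- setNames(excluded$reason, excluded$gene_id)
  trace <- add_filter_stage(trace, "testable",
                            intersect(trace$retained, summary$gene_id),
                            reasons)

  breakdown <- group_breakdown(
    parental_kept |> filter(.data$gene_id %in% summary$gene_id), config
  )

  structure(
    list(summary = summary, breakdown = breakdown, trace = trace,
         snps = snps_inf |> filter(.data$snp_id %in% cov$snp_id[cov$pass]),
         calls = calls, parental_counts = parental_kept, config = config),
    class = "poe_result"
  )
}

#' @export
print.poe_result <- function(x, ...) {
  cat("<poe_result>\n")
  print(x$trace)
  print(x$summary)
  invisible(x)
}

#' Recover simulated truth against pipeline output
#'
#' Convenience for simulation studies: joins a cohort's truth ledger to a
#' fitted summary and reports, per gene, the true and called class.
#'
#' @param result A `"poe_result"` from [poe_pipeline()] (or a
#'   `"poe_summary"`).
#' @param truth The `truth` element of a [sim_cohort()].
#' @return Tibble with `gene_id`, `theta`, `true_class`, `called_class`
#'   (`NA` when the gene did not reach testing), and `correct`.
#' @export
score_class_recovery <- function(result, truth) {
  summary <- if (inherits(result, "poe_result")) result$summary else result
  truth$genes |>
    left_join(summary |> select("gene_id", called_class = "class"),
              by = "gene_id") |>
    mutate(correct = !is.na(.data$called_class) &
             as.character(.data$called_class) == as.character(.data$true_class))
}
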
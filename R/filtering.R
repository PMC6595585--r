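#' Median-of-ratios size factors
#'
#' Computes one positive scaling factor per sample from a raw count matrix:
#' for each gene expressed in every sample, the ratio of its count to its
#' geometric mean across samples is taken, and the sample's factor is the
#' median of those ratios. Columns that are exact scalar multiples of each
#' other recover those scalars up to a common constant.
#'
#' @param gene_counts Tibble with a `gene_id` column and one raw count column
#'   per sample (as from [read_gene_counts()]), or a numeric matrix with gene
#'   rownames.
#' @return Named numeric vector of size factors, one per sample.
#' @export
compute_size_factors <- function(gene_counts) {
  m <- gene_counts_matrix(gene_counts)
  log_m <- log(m)
  finite <- rowSums(is.finite(log_m)) == ncol(m)
  if (!any(finite)) {
    abort(paste("no gene has nonzero counts in all samples;",
                "consider a pseudo-reference fallback"))
  }
  log_geo <- rowMeans(log_m[finite, , drop = FALSE])
  apply(log_m[finite, , drop = FALSE], 2, function(col) exp(median(col - log_geo)))
}

gene_counts_matrix <- function(gene_counts) {
  if (is.matrix(gene_counts)) return(gene_counts)
  m <- as.matrix(gene_counts[setdiff(names(gene_counts), "gene_id")])
  rownames(m) <- gene_counts$gene_id
  m
}

#' Normalize a count matrix by size factors
#'
#' @inheritParams compute_size_factors
#' @param size_factors Named vector from [compute_size_factors()]; computed
#'   if omitted.
#' @return Matrix of normalized counts (counts divided by their sample's
#'   factor), genes in rows.
#' @export
normalize_counts <- function(gene_counts, size_factors = NULL) {
  m <- gene_counts_matrix(gene_counts)
  size_factors <- size_factors %||% compute_size_factors(gene_counts)
  sweep(m, 2, size_factors[colnames(m)], "/")
}

#' Expression filter on median normalized counts
#'
#' A gene is retained iff its median normalized count across samples reaches
#' `threshold`; genes with median strictly below are flagged as having
#' limited expression.
#'
#' @inheritParams normalize_counts
#' @param threshold Minimum median normalized read count (default 50).
#' @return Tibble with columns `gene_id`, `median_normalized`, `retained`.
#' @export
filter_genes_by_expression <- function(gene_counts, threshold = 50,
                                       size_factors = NULL) {
  norm <- normalize_counts(gene_counts, size_factors)
  med <- apply(norm, 1, median)
  tibble(gene_id = rownames(norm), median_normalized = unname(med),
         retained = unname(med >= threshold))
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = reads * 1e9 / (length_bp * total_mapped_reads)`.
#'
#' @param gene_reads Read count(s) assigned to the gene.
#' @param gene_length_bp Transcript length in bp (> 0).
#' @param total_mapped_reads Library size (> 0).
#' @return Numeric vector of FPKM values.
#' @examples
#' compute_fpkm(1000, 1000, 1e6) # 1000
#' @export
compute_fpkm <- function(gene_reads, gene_length_bp, total_mapped_reads) {
  if (any(gene_length_bp <= 0) || any(total_mapped_reads <= 0)) {
    abort("gene_length_bp and total_mapped_reads must be positive")
  }
  gene_reads * 1e9 / (gene_length_bp * total_mapped_reads)
}

#' Cohort minor allele frequency at one SNP
#'
#' Alleles are tallied over non-missing genotypes; the MAF is
#' `min(p, 1 - p)`. Invariant to swapping the ref/alt labels.
#'
#' @param genotypes Vector (factor or character) of genotypes in
#'   hom_ref/het/hom_alt/missing.
#' @return The minor allele frequency in \[0, 0.5\].
#' @export
compute_maf <- function(genotypes) {
  g <- as.character(genotypes)
  g <- g[!is.na(g) & g != "missing"]
  if (length(g) == 0L) abort("all genotypes missing; MAF undefined")
  alt <- sum(c(hom_ref = 0, het = 1, hom_alt = 2)[g])
  p_alt <- alt / (2 * length(g))
  min(p_alt, 1 - p_alt)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness of fit of the observed genotype counts
#' against p^2 / 2pq / q^2 expectations at the sample allele frequency.
#' Monomorphic SNPs carry no testable departure and return p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return The chi-square p-value.
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) abort("hwe_test needs at least one genotype")
  p <- (2 * n_hom_ref + n_het) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(n_hom_ref, n_het, n_hom_alt) - expected)^2 / expected)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Assign SNPs to genes by exon intersection and apply curation exclusions
#'
#' A SNP is retained iff its 1-based position falls inside at least one exon
#' interval (`start < pos <= end` on the same chromosome) of exactly one gene
#' and it is not on the exclusion list. The exclusion list stands in for
#' manual curation of SNPs lying in alternative exons that overlap introns of
#' a gene's main transcript. If `sites` already carries a `gene_id` column the
#' assignment is checked against that gene's exons instead; a pre-assigned
#' gene with no exon records drops the SNP with reason `"unannotated"`.
#'
#' @param sites Tibble of SNPs (`snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   optionally `gene_id`).
#' @param exons Tibble from [read_exon_bed()].
#' @param exclusion_list Character vector of SNP ids to drop.
#' @return List with `snps` (retained sites with `gene_id`) and `dropped`
#'   (tibble `snp_id`, `reason` in unannotated / not_exonic / ambiguous_gene /
#'   manual_exclusion).
#' @export
select_exonic_snps <- function(sites, exons, exclusion_list = character()) {
  sites <- as_tibble(sites)
  pre_assigned <- "gene_id" %in% names(sites)
  if (pre_assigned) {
    hits <- sites |>
      left_join(exons, by = c("chrom", "gene_id"),
                relationship = "many-to-many") |>
      mutate(inside = !is.na(.data$start) & snp_in_exon(.data$pos, .data$start, .data$end),
             annotated = .data$gene_id %in% exons$gene_id) |>
      group_by(.data$snp_id, .data$gene_id) |>
      summarise(inside = any(.data$inside), annotated = any(.data$annotated),
                .groups = "drop")
    status <- hits |>
      mutate(reason = case_when(
        !.data$annotated ~ "unannotated",
        !.data$inside ~ "not_exonic",
        TRUE ~ NA_character_
      ))
  } else {
    hits <- sites |>
      left_join(exons, by = "chrom", relationship = "many-to-many") |>
      mutate(inside = !is.na(.data$gene_id) & snp_in_exon(.data$pos, .data$start, .data$end)) |>
      group_by(.data$snp_id) |>
      summarise(n_genes = n_distinct(.data$gene_id[.data$inside]),
                gene_id = if (n_genes == 1L) .data$gene_id[.data$inside][1] else NA_character_,
                .groups = "drop")
    status <- hits |>
      mutate(reason = case_when(
        .data$n_genes == 0L ~ "not_exonic",
        .data$n_genes > 1L ~ "ambiguous_gene",
        TRUE ~ NA_character_
      ))
  }
  status <- status |>
    mutate(reason = ifelse(is.na(.data$reason) & .data$snp_id %in% exclusion_list,
                           "manual_exclusion", .data$reason))
  keep_ids <- status$snp_id[is.na(status$reason)]
  gene_of <- setNames(status$gene_id, status$snp_id)
  snps <- sites |>
    filter(.data$snp_id %in% keep_ids)
  if (!pre_assigned) snps <- mutate(snps, gene_id = unname(gene_of[.data$snp_id]))
  list(
    snps = snps,
    dropped = status |> filter(!is.na(.data$reason)) |>
      select("snp_id", "reason") |> arrange(.data$snp_id)
  )
}

# ---- filter trace -----------------------------------------------------------

new_filter_trace <- function(candidates) {
  structure(
    list(
      stages = tibble(stage = character(), n_in = integer(), n_out = integer()),
      dropped = tibble(stage = character(), gene_id = character(),
                       reason = character()),
      candidates = candidates,
      retained = candidates
    ),
    class = "poe_filter_trace"
  )
}

add_filter_stage <- function(trace, stage, retained, reasons) {
  genes_in <- trace$retained
  dropped_ids <- setdiff(genes_in, retained)
  if (!all(retained %in% genes_in)) {
    abort("filter stages must be nested: retained set not a subset of input")
  }
  if (length(dropped_ids)) {
    if (is.null(names(reasons))) reasons <- setNames(rep_len(reasons, length(dropped_ids)), dropped_ids)
    trace$dropped <- bind_rows(trace$dropped, tibble(
      stage = stage, gene_id = dropped_ids,
      reason = unname(reasons[dropped_ids])
    ))
  }
  trace$stages <- bind_rows(trace$stages, tibble(
    stage = stage, n_in = length(genes_in), n_out = length(retained)
  ))
  trace$retained <- retained
  trace
}

#' @export
print.poe_filter_trace <- function(x, ...) {
  cat("<poe_filter_trace>", length(x$candidates), "candidate genes ->",
      length(x$retained), "retained\n")
  print(x$stages)
  invisible(x)
}

#' Gene- and SNP-level candidate filtering cascade
#'
#' Runs the pre-phasing filter stages over a candidate gene panel:
#' \describe{
#'   \item{annotation}{a gene must have exon records;}
#'   \item{expression}{median normalized expression at or above the
#'     configured threshold (median-of-ratios normalization);}
#'   \item{common_exonic_snp}{the gene must carry at least one genotyped SNP
#'     that is exonic for exactly that gene, not manually excluded, has cohort
#'     MAF strictly above the threshold, and shows no Hardy-Weinberg
#'     departure (chi-square p strictly above `hwe_alpha`).}
#' }
#' The later informative-family and read-coverage stages need phased allelic
#' counts and are appended to the same trace by [poe_pipeline()].
#'
#' @param genotypes Genotype tibble from [read_genotypes()] (with sites).
#' @param gene_counts Gene count tibble from [read_gene_counts()].
#' @param exons Exon tibble from [read_exon_bed()].
#' @param config A [poe_config()].
#' @return List with `snps` (retained SNPs with gene assignment and per-SNP
#'   `maf`, `hwe_p`), `snp_dropped` (SNP-level dropout reasons), and `trace`
#'   (a `poe_filter_trace`: `$stages`, `$dropped`, `$retained`).
#' @export
filter_candidates <- function(genotypes, gene_counts, exons,
                              config = poe_config()) {
  config <- as_poe_config(config)
  candidates <- gene_counts$gene_id
  trace <- new_filter_trace(candidates)

  # annotation: the gene must have exon records
  annotated <- candidates[candidates %in% exons$gene_id]
  trace <- add_filter_stage(trace, "annotation", annotated, "unannotated")

  # expression: median normalized >= threshold
  expr <- filter_genes_by_expression(gene_counts,
                                     config$expression_median_threshold)
  expressed <- intersect(annotated, expr$gene_id[expr$retained])
  trace <- add_filter_stage(trace, "expression", expressed, "low_expression")

  # SNP level: exonic location, exclusion list, MAF, HWE
  sites <- snp_sites(genotypes)
  sel <- select_exonic_snps(sites, exons, config$snp_exclusion_list)
  snp_stats <- genotypes |>
    filter(.data$snp_id %in% sel$snps$snp_id) |>
    group_by(.data$snp_id) |>
    summarise(
      n_nonmissing = sum(.data$genotype != "missing"),
      maf = if (n_nonmissing > 0) compute_maf(.data$genotype) else NA_real_,
      hwe_p = if (n_nonmissing > 0) {
        hwe_test(sum(.data$genotype == "hom_ref"), sum(.data$genotype == "het"),
                 sum(.data$genotype == "hom_alt"))
      } else NA_real_,
      .groups = "drop"
    )
  snps <- sel$snps |>
    left_join(snp_stats, by = "snp_id") |>
    mutate(
      snp_reason = case_when(
        is.na(.data$maf) ~ "all_missing",
        .data$maf <= config$maf_threshold ~ "low_maf",
        .data$hwe_p <= config$hwe_alpha ~ "hwe_violation",
        TRUE ~ NA_character_
      )
    )
  snp_dropped <- bind_rows(
    sel$dropped,
    snps |> filter(!is.na(.data$snp_reason)) |>
      select("snp_id", reason = "snp_reason")
  ) |> arrange(.data$snp_id)
  snps_ok <- snps |> filter(is.na(.data$snp_reason)) |> select(-"snp_reason")

  with_snp <- intersect(expressed, unique(snps_ok$gene_id))
  trace <- add_filter_stage(trace, "common_exonic_snp", with_snp,
                            "no_common_exonic_snp")

  list(
    snps = snps_ok |> filter(.data$gene_id %in% with_snp),
    snp_dropped = snp_dropped,
    trace = trace
  )
}
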
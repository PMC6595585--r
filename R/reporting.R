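#' Row-wise z-score standardization
#'
#' Standardizes each gene (row) of an expression matrix by subtracting its
#' mean across samples and dividing by its standard deviation across samples
#' (population convention, denominator n), so every row has mean 0 and SD 1.
#' Zero-variance rows are emitted as all zeros with a warning.
#'
#' @param mat Numeric matrix, genes in rows (typically log-transformed
#'   normalized counts).
#' @return Matrix of the same shape.
#' @export
zscore_standardize <- function(mat) {
  mu <- rowMeans(mat)
  sd_pop <- sqrt(rowMeans((mat - mu)^2))
  flat <- sd_pop == 0
  if (any(flat)) {
    warn(paste("zero-variance row(s) emitted as zeros:",
               paste(utils::head(rownames(mat)[flat] %||% which(flat), 5),
                     collapse = ", ")))
    sd_pop[flat] <- 1
  }
  out <- (mat - mu) / sd_pop
  out[flat, ] <- 0
  out
}

#' Deterministic hierarchical ordering by Minkowski distance
#'
#' Agglomerative clustering (average linkage) on Minkowski distances of the
#' given power, returning row and column display orders. Ties are broken by
#' first-seen index, so the ordering is deterministic given the input order.
#'
#' @param mat Numeric matrix (>= 2 rows).
#' @param p Minkowski power (2 = Euclidean).
#' @return List with `row_order`, `col_order` (integer permutations) and the
#'   two `hclust` trees (`row_tree`, `col_tree`; `col_tree` is `NULL` for
#'   single-column matrices).
#' @export
hierarchical_order <- function(mat, p = 2) {
  if (nrow(mat) < 2L) abort("hierarchical_order needs at least 2 rows")
  row_tree <- hclust(dist(mat, method = "minkowski", p = p),
                     method = "average")
  col_tree <- if (ncol(mat) >= 2L) {
    hclust(dist(t(mat), method = "minkowski", p = p), method = "average")
  }
  list(
    row_order = row_tree$order,
    col_order = if (is.null(col_tree)) seq_len(ncol(mat)) else col_tree$order,
    row_tree = row_tree,
    col_tree = col_tree
  )
}

#' Build the per-gene catalog
#'
#' Joins the gene-level classification, the per-clinical-group parental
#' proportions, per-group normalized expression (median and IQR) and
#' cohort-wide FPKM statistics into one table, one row per gene and clinical
#' group, ordered trim1, trim2, trim3_normal, SGA, LGA, PE, GD.
#'
#' @param summary A `"poe_summary"` tibble.
#' @param breakdown Output of [group_breakdown()].
#' @param gene_counts Gene count tibble (for normalized expression stats);
#'   optional.
#' @param pedigree Pedigree tibble mapping placenta samples to groups
#'   (required with `gene_counts`).
#' @param gene_lengths Named vector of transcript lengths in bp (for FPKM);
#'   optional.
#' @return Tibble with one row per (gene, clinical group).
#' @export
build_catalog <- function(summary, breakdown, gene_counts = NULL,
                          pedigree = NULL, gene_lengths = NULL) {
  cat_tbl <- breakdown |>
    inner_join(summary |>
                 select("gene_id", "class", "expressed_parent",
                        overall_mat_proportion = "mat_proportion",
                        "p_corr"),
               by = "gene_id")
  if (!is.null(gene_counts)) {
    if (is.null(pedigree)) abort("pedigree is required to group expression stats")
    norm <- normalize_counts(gene_counts)
    expr_long <- as_tibble(norm, rownames = "gene_id") |>
      tidyr::pivot_longer(-"gene_id", names_to = "placenta",
                          values_to = "normalized") |>
      inner_join(pedigree |> select("placenta", "clinical_group"),
                 by = "placenta")
    expr_stats <- expr_long |>
      group_by(.data$gene_id, .data$clinical_group) |>
      summarise(expr_median = median(.data$normalized),
                expr_iqr = stats::IQR(.data$normalized), .groups = "drop")
    cat_tbl <- cat_tbl |>
      left_join(expr_stats, by = c("gene_id", "clinical_group"))
    if (!is.null(gene_lengths)) {
      raw <- gene_counts_matrix(gene_counts)
      total_reads <- colSums(raw)
      fpkm <- sweep(raw * 1e9 / gene_lengths[rownames(raw)], 2, total_reads, "/")
      fpkm_stats <- tibble(gene_id = rownames(raw),
                           fpkm_mean = rowMeans(fpkm),
                           fpkm_sd = apply(fpkm, 1, sd))
      cat_tbl <- cat_tbl |> left_join(fpkm_stats, by = "gene_id")
    }
  }
  cat_tbl |> arrange(.data$gene_id, .data$clinical_group)
}

#' Export the analysis catalog to TSV files
#'
#' Writes `gene_summary.tsv` (one row per tested gene), `group_catalog.tsv`
#' (gene by clinical group) and `class_summary.tsv` (per-class medians) with
#' a deterministic column order, and logs the per-class gene counts. Re-runs
#' on identical inputs are byte-identical.
#'
#' @param summary A `"poe_summary"` tibble.
#' @param catalog Output of [build_catalog()] (or [group_breakdown()]).
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
export_catalog <- function(summary, catalog, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene_summary = file.path(out_dir, "gene_summary.tsv"),
    group_catalog = file.path(out_dir, "group_catalog.tsv"),
    class_summary = file.path(out_dir, "class_summary.tsv")
  )
  readr::write_tsv(as_tibble(summary), paths[["gene_summary"]])
  readr::write_tsv(catalog, paths[["group_catalog"]])
  readr::write_tsv(class_medians(summary), paths[["class_summary"]])
  counts <- table(summary$class)
  inform(paste0("catalog written: ",
                paste(names(counts), as.integer(counts), sep = "=",
                      collapse = ", ")))
  invisible(paths)
}
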
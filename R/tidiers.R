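#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gene-level parental expression summary
#'
#' @param x A `"poe_summary"` tibble.
#' @param ... Unused.
#' @return A plain tibble (one row per tested gene) with the class attributes
#'   stripped.
#' @method tidy poe_summary
#' @export
tidy.poe_summary <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "n_tests") <- NULL
  attr(out, "config") <- NULL
  attr(out, "excluded") <- NULL
  attr(out, "snp_coverage") <- NULL
  class(out) <- setdiff(class(out), "poe_summary")
  out
}

#' One-row overview of a parental expression analysis
#'
#' @param x A `"poe_summary"` tibble.
#' @param ... Unused.
#' @return A one-row tibble: genes tested, Bonferroni divisor, genes
#'   excluded before testing, and per-class gene counts.
#' @method glance poe_summary
#' @export
glance.poe_summary <- function(x, ...) {
  counts <- table(x$class)
  tibble(
    n_genes_tested = nrow(x),
    n_tests_bonferroni = attr(x, "n_tests"),
    n_excluded = nrow(attr(x, "excluded") %||% tibble()),
    n_imprinted = as.integer(counts[["imprinted"]]),
    n_biased = as.integer(counts[["biased"]]),
    n_biallelic = as.integer(counts[["biallelic"]])
  )
}

#' @export
print.poe_summary <- function(x, ...) {
  counts <- table(x$class)
  cat("<poe_summary> ", nrow(x), " genes tested (Bonferroni m = ",
      attr(x, "n_tests"), "): ",
      paste(names(counts), as.integer(counts), sep = " ", collapse = ", "),
      "\n", sep = "")
  NextMethod()
}

#' Plot maternal read proportions with confidence intervals
#'
#' One point per gene (maternal read proportion with its confidence
#' interval), coloured by class, with the classification thresholds drawn as
#' reference lines.
#'
#' @param object A `"poe_summary"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot poe_summary
#' @export
autoplot.poe_summary <- function(object, ...) {
  cfg <- attr(object, "config") %||% poe_config()
  df <- as_tibble(object) |>
    mutate(gene_id = factor(.data$gene_id,
                            levels = .data$gene_id[order(.data$mat_proportion)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mat_proportion, y = .data$gene_id,
                                   colour = .data$class)) +
    ggplot2::geom_vline(xintercept = c(1 - cfg$imprinted_threshold,
                                       1 - cfg$biased_low, 0.5,
                                       cfg$biased_low, cfg$imprinted_threshold),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.3) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Maternal read proportion", y = NULL, colour = "Class") +
    ggplot2::theme_minimal()
}

#' Plot per-group parental proportions for selected genes
#'
#' The per-gene catalog view: maternal read proportion per clinical subgroup
#' with confidence intervals, faceted by gene, to inspect the stability of
#' parental expression across gestation and pregnancy complications.
#'
#' @param breakdown Output of [group_breakdown()].
#' @param genes Optional character vector of genes to show (defaults to all).
#' @return A ggplot object.
#' @export
plot_group_catalog <- function(breakdown, genes = NULL) {
  df <- breakdown
  if (!is.null(genes)) df <- df |> filter(.data$gene_id %in% genes)
  df <- df |> filter(!is.na(.data$mat_proportion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clinical_group,
                                   y = .data$mat_proportion)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.2, colour = "grey40") +
    ggplot2::geom_point(size = 1.6, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Maternal read proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Expression heatmap of classified genes
#'
#' Log2(normalized count + 1) expression, z-scored per gene, with rows
#' (genes) and columns (samples) ordered by average-linkage clustering on
#' Minkowski distance; genes are grouped by parental expression class.
#'
#' @param summary A `"poe_summary"` tibble.
#' @param gene_counts Gene count tibble.
#' @param pedigree Pedigree tibble (orders samples within clinical groups).
#' @param p Minkowski power.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(summary, gene_counts, pedigree, p = 2) {
  norm <- normalize_counts(gene_counts)
  norm <- norm[rownames(norm) %in% summary$gene_id, , drop = FALSE]
  z <- zscore_standardize(log2(norm + 1))
  df <- as_tibble(z, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "placenta", values_to = "z") |>
    inner_join(summary |> select("gene_id", "class"), by = "gene_id") |>
    inner_join(pedigree |> select("placenta", "clinical_group"),
               by = "placenta")
  ord <- hierarchical_order(z, p = p)
  df <- df |>
    mutate(gene_id = factor(.data$gene_id, levels = rownames(z)[ord$row_order]),
           placenta = factor(.data$placenta, levels = colnames(z)[ord$col_order]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$placenta, y = .data$gene_id,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(class ~ clinical_group, scales = "free",
                        space = "free") +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", name = "Row z-score") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
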
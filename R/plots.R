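#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_line facet_wrap
#'   labs theme_minimal scale_size_area
NULL

#' Plot PCA gene scores
#'
#' Scatter of the first two principal components, one dot per gene, axes
#' labeled with the variance fraction each component explains. Optionally
#' colored by SOM unit.
#'
#' @param object a `gene_pca`.
#' @param som_fit optional `som_fit` to color genes by map unit.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gene_pca <- function(object, som_fit = NULL, ...) {
  d <- tidy(object, "scores")
  if (!is.null(som_fit)) {
    d <- left_join(d, tidy(som_fit)[, c("gene_id", "unit")], by = "gene_id")
    d$unit <- factor(d$unit)
  }
  p <- ggplot(d, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point(if (is.null(som_fit)) aes() else aes(color = .data$unit),
               size = 0.8, alpha = 0.7) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2]),
         color = "SOM unit") +
    theme_minimal()
  p
}

#' Plot per-unit SOM expression profiles
#'
#' Mean scaled expression of each unit's member genes across tissue classes,
#' faceted by unit — a line-plot rendering of the map's code/sector display.
#'
#' @param object a `som_fit`.
#' @param sm the `scaled_matrix` the fit was trained on.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.som_fit <- function(object, sm, ...) {
  d <- som_summarize(object, sm)
  d$column <- factor(d$column, levels = unique(d$column))
  ggplot(filter(d, .data$n_genes > 0),
         aes(x = .data$column, y = .data$mean_scaled, group = .data$unit)) +
    geom_line() +
    geom_point(size = 0.8) +
    facet_wrap(~unit, labeller = ggplot2::label_both) +
    labs(x = NULL, y = "mean scaled expression") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a module partition's size distribution
#'
#' @param object a `module_partition`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.module_partition <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::count(.data$module, name = "n_genes")
  ggplot(d, aes(x = factor(.data$module), y = .data$n_genes)) +
    geom_col() +
    labs(x = "module", y = "genes",
         subtitle = sprintf("Q = %.3f", object$modularity)) +
    theme_minimal()
}

#' Plot enrichment results
#'
#' Top terms by FDR for each module (or for one result table).
#'
#' @param enr tibble from [enrich_terms()] (optionally with a `module`
#'   column).
#' @param max_terms terms shown per panel.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(enr, max_terms = 10) {
  d <- enr |>
    (\(x) if ("module" %in% names(x)) group_by(x, .data$module) else x)() |>
    dplyr::slice_min(.data$fdr, n = max_terms, with_ties = FALSE) |>
    ungroup()
  p <- ggplot(d, aes(x = -log10(.data$fdr),
                     y = stats::reorder(.data$term_name, -.data$fdr))) +
    geom_col() +
    labs(x = "-log10 FDR", y = NULL) +
    theme_minimal()
  if ("module" %in% names(d)) {
    p <- p + facet_wrap(~module, scales = "free_y",
                        labeller = ggplot2::label_both)
  }
  p
}
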
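#' Manhattan plot of an association scan
#'
#' @param res a `qt_assoc` from [assoc_scan()].
#' @param p_thresh significance line drawn at `-log10(p_thresh)`.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(res, p_thresh = 1e-4) {
  tab <- manhattan_table(res)
  tab$chrom <- factor(tab$chrom, levels = unique(tab$chrom))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pos, y = .data$neg_log10_p,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(p_thresh), linetype = "dashed") +
    ggplot2::facet_grid(~ chrom, scales = "free_x", space = "free_x",
                        switch = "x") +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p)),
                  title = res$module) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
}

#' @method autoplot qt_assoc
#' @export
autoplot.qt_assoc <- function(object, ...) plot_manhattan(object, ...)

#' Heat map of the structure correlation matrix with module annotation
#'
#' @param C correlation matrix from [structure_correlation()].
#' @param partition optional `module_partition`; phenotypes are ordered by
#'   the clustering tree when given.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(C, partition = NULL) {
  ord <- if (!is.null(partition)) {
    partition$tree$labels[partition$tree$order]
  } else {
    rownames(C)
  }
  df <- tibble::as_tibble(C, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "r") |>
    dplyr::mutate(row = factor(.data$row, ord),
                  col = factor(.data$col, ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$row, .data$col,
                                   fill = abs(.data$r))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#b2182b", high = "#2166ac",
                                 limits = c(0, 1), name = "|r|") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' @method autoplot module_partition
#' @export
autoplot.module_partition <- function(object, C, ...) {
  plot_correlation_heatmap(C, object)
}
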
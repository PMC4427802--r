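#' Plot methods
#'
#' `autoplot()` methods render the standard views: a volcano plot for a
#' `de_table`, a score scatter for a `pca_result`, and a clipped z-score
#' heatmap (with dendrogram leaf ordering) for a `cluster_result`.
#' `plot_top_proteins()` draws per-group box plots from
#' [top_protein_boxes()] output.
#'
#' @param object A `de_table`, `pca_result` or `cluster_result`.
#' @param cutoff Significance cutoff for the volcano flag (default: the
#'   table's selection alpha).
#' @param ... Unused.
#' @return A ggplot object.
#' @name serodiff-plots
NULL

#' @rdname serodiff-plots
#' @method autoplot de_table
#' @export
autoplot.de_table <- function(object, cutoff = attr(object, "alpha"), ...) {
  pts <- volcano(object, cutoff = cutoff)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log2_fc, y = .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$de), size = 1, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "grey55"),
      name = sprintf("p < %.3g (all folds)", cutoff)
    ) +
    ggplot2::geom_hline(yintercept = -log10(cutoff), linetype = "dashed") +
    ggplot2::labs(
      x = "log2 fold change (CCA - BBTD)",
      y = expression(-log[10] ~ "max fold p")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname serodiff-plots
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, ...) {
  sc <- object$scores
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' @rdname serodiff-plots
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  disp <- object$display
  disp$sample_id <- factor(disp$sample_id, levels = object$sample_order)
  disp$protein <- factor(disp$protein, levels = object$protein_order)
  ggplot2::ggplot(disp, ggplot2::aes(x = .data$sample_id, y = .data$protein, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#1a9641", mid = "black", high = "#d7191c",
      limits = c(-object$clip, object$clip), name = "z"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1),
      axis.text.y = ggplot2::element_blank()
    ) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname serodiff-plots
#' @param boxes Output of [top_protein_boxes()].
#' @export
plot_top_proteins <- function(boxes, ...) {
  ggplot2::ggplot(boxes, ggplot2::aes(x = .data$group, fill = .data$group)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(
        ymin = .data$min, lower = .data$q1, middle = .data$median,
        upper = .data$q3, ymax = .data$max
      ),
      stat = "identity"
    ) +
    ggplot2::facet_wrap(~protein, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "normalized log2 intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
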
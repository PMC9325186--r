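# ggplot2 views of the main result types.

#' Volcano plot of a differential analysis
#'
#' log2 fold change against -log10 p-value, highlighting features that pass
#' the signature fold-change floor at the given q-value threshold.
#'
#' @param results A `besig_diff` tibble.
#' @param min_abs_lfc Fold-change floor to highlight (log2).
#' @param q_threshold BH q-value threshold to highlight.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, min_abs_lfc = 0.75, q_threshold = 0.1) {
  df <- as_tibble(results)
  df$status <- ifelse(
    abs(df$log2fc) >= min_abs_lfc & df$q_value < q_threshold,
    ifelse(df$log2fc > 0, "up in BE", "down in BE"), "ns"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      "up in BE" = "#c0392b", "down in BE" = "#2980b9", "ns" = "grey70"
    )) +
    ggplot2::geom_vline(xintercept = c(-min_abs_lfc, min_abs_lfc), linetype = "dashed") +
    ggplot2::labs(
      x = "log2 fold change (BE - adjacent)", y = "-log10 p-value",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of signature features across samples
#'
#' Tile display of a (typically standardized, signature-projected) matrix
#' with samples ordered by the clustering dendrogram.
#'
#' @param x An [intensity_tbl()], e.g. from [project_signature()].
#' @param clust Optional `besig_clust`; its tree fixes the sample order.
#' @return A ggplot object.
#' @export
plot_signature_heatmap <- function(x, clust = NULL) {
  v <- intensity_values(x)
  ord <- if (!is.null(clust)) clust$tree$labels[clust$tree$order] else colnames(v)
  df <- as_tibble(v, rownames = "feature_id") %>%
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "value")
  df$sample_id <- factor(df$sample_id, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$feature_id,
    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2980b9", mid = "white", high = "#c0392b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
#' @method autoplot besig_gsea
#' @importFrom ggplot2 autoplot
autoplot.besig_gsea <- function(object, fdr_threshold = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- df$fdr < fdr_threshold
  df$set_name <- factor(df$set_name, levels = df$set_name[order(df$nes)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set_name,
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey70")) +
    ggplot2::labs(x = "Normalized enrichment score", y = NULL,
      fill = sprintf("FDR < %.2g", fdr_threshold)) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot besig_ksea
autoplot.besig_ksea <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- df$p_value < alpha
  df$kinase <- factor(df$kinase, levels = df$kinase[order(df$z)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$kinase,
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#8e44ad", `FALSE` = "grey70")) +
    ggplot2::labs(x = "Kinase enrichment z-score (positive = BE)", y = NULL,
      fill = sprintf("p < %.2g", alpha)) +
    ggplot2::theme_minimal()
}
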
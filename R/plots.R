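#' Expression heatmap ordered by cluster
#'
#' max1 values, one row per gene, rows grouped by hard cluster assignment,
#' columns tissue-major / time-minor — the standard overview of the fuzzy
#' clustering.
#'
#' @param model A [fuzzy_kmeans()] fit.
#' @param x The matrix the model was fitted on.
#' @return A ggplot object.
#' @export
plot_cluster_heatmap <- function(model, x) {
  asg <- assign_clusters(model)
  ord <- asg$gene_id[order(asg$cluster, -asg$membership)]
  df <- tibble::as_tibble(x, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample",
                        values_to = "max1") |>
    dplyr::mutate(gene_id = factor(.data$gene_id, levels = rev(ord)),
                  sample = factor(.data$sample, levels = colnames(x)))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$gene_id,
                                   fill = .data$max1)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "yellow") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "genes (by cluster)", fill = "max1")
}

#' @export
autoplot.fuzzy_kmeans <- function(object, x = NULL, ...) {
  cen <- tibble::as_tibble(object$centroids) |>
    stats::setNames(object$colnames) |>
    dplyr::mutate(cluster = factor(seq_len(object$k))) |>
    tidyr::pivot_longer(-"cluster", names_to = "sample") |>
    tidyr::separate_wider_delim("sample", ":", names = c("tissue", "time")) |>
    dplyr::mutate(time = as.integer(.data$time))
  ggplot2::ggplot(cen, ggplot2::aes(.data$time, .data$value,
                                    colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = "centroid (max1)", x = "time point")
}

#' Signed TF enrichment heatmap
#'
#' Yellow for enrichment (`-log10 p`), magenta for depletion, gray for
#' non-significant cells.
#'
#' @param heat Matrix from [build_tf_heatmap()].
#' @return A ggplot object.
#' @export
plot_tf_heatmap <- function(heat) {
  df <- tibble::as_tibble(heat, rownames = "tf") |>
    tidyr::pivot_longer(-"tf", names_to = "cell", values_to = "heat") |>
    dplyr::mutate(cell = factor(.data$cell, levels = colnames(heat)),
                  tf = factor(.data$tf, levels = rev(rownames(heat))))
  ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$tf,
                                   fill = .data$heat)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "magenta", mid = "white",
                                  high = "gold", na.value = "grey80") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = "tissue:time", y = NULL, fill = "signed -log10 p")
}

#' Expression-distance distributions by pair orientation
#'
#' @param pairs Output of [pair_expression_distance()].
#' @return A ggplot object (boxplots per orientation class).
#' @export
plot_orientation_distances <- function(pairs) {
  lv <- c("operon", "head_to_head", "head_to_tail", "tail_to_tail", "random")
  df <- pairs |>
    dplyr::filter(!is.na(.data$expression_distance)) |>
    dplyr::mutate(orientation = factor(.data$orientation, levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$orientation,
                                   .data$expression_distance)) +
    ggplot2::geom_boxplot() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "35-D expression distance")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
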
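# ggplot2 visual summaries of the main result types.

#' MA plot of gene statistics with DEG highlighting
#'
#' @param stats Gene statistics tibble (`a_value`, `m_value`).
#' @param selection Optional `deg_selection` used to color DEGs.
#' @param a_min Expression-filter threshold drawn as a guide line.
#' @return A ggplot.
#' @export
plot_ma <- function(stats, selection = NULL, a_min = 0.5) {
  df <- dplyr::mutate(stats, status = "other")
  if (!is.null(selection)) {
    df$status[df$gene_id %in% selection$up] <- "up"
    df$status[df$gene_id %in% selection$down] <- "down"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$a_value, .data$m_value,
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = a_min, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      up = "#D55E00", down = "#0072B2", other = "grey60")) +
    ggplot2::labs(x = "average log2 CPM (a value)",
                  y = "log2 fold change (m value)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' DE-score waterfall plot
#'
#' Genes ordered by rank with the composite DE score on the y axis.
#'
#' @param scored A `scored_genes` tibble.
#' @return A ggplot.
#' @export
plot_de_score <- function(scored) {
  ggplot2::ggplot(scored, ggplot2::aes(.data$rank, .data$de_score)) +
    ggplot2::geom_col(width = 1,
                      ggplot2::aes(fill = .data$de_score > 0),
                      show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00",
                                          `FALSE` = "#0072B2")) +
    ggplot2::labs(x = "rank", y = "DE score") +
    ggplot2::theme_minimal()
}

#' Plot a resampling report
#'
#' Jaccard histograms for bootstrap/subsample reports; the null-statistic
#' histogram with the observed value for permutation reports.
#'
#' @param object A `resample_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot resample_report
#' @export
autoplot.resample_report <- function(object, ...) {
  if (object$scheme == "permutation") {
    df <- tibble::tibble(t_null = object$t_null)
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$t_null)) +
        ggplot2::geom_histogram(bins = 30, fill = "grey70") +
        ggplot2::geom_vline(xintercept = object$t_observed,
                            colour = "#D55E00") +
        ggplot2::labs(x = "null statistic (mean |DE score| of DEGs)",
                      y = "count",
                      title = sprintf("permutation null (p = %.4f)",
                                      object$empirical_p)) +
        ggplot2::theme_minimal())
  }
  df <- tidyr::pivot_longer(tidy(object),
                            dplyr::all_of(c("jaccard_up",
                                            "jaccard_down")),
                            names_to = "direction",
                            values_to = "jaccard")
  ggplot2::ggplot(df, ggplot2::aes(.data$jaccard,
                                   fill = .data$direction)) +
    ggplot2::geom_histogram(bins = 20, position = "identity",
                            alpha = 0.6) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Jaccard index vs full-data DEGs", y = "count",
                  title = sprintf("%s reproducibility", object$scheme)) +
    ggplot2::theme_minimal()
}

#' Plot a separation report (PCA scores with separation statistics)
#'
#' @param object A `separation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot separation_report
#' @export
autoplot.separation_report <- function(object, ...) {
  sc <- object$pca$scores
  vf <- object$pc_variance_fractions
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                   label = .data$sample_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * vf[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * vf[2]),
      title = sprintf("PERMANOVA R2 = %.3f (p = %.3f), ANOSIM R = %.2f",
                      object$permanova_R2, object$permanova_p,
                      object$anosim_R)) +
    ggplot2::theme_minimal()
}

#' Cross-species DE-score scatter plot
#'
#' @param join An `xspecies_join`.
#' @return A ggplot.
#' @export
plot_xspecies <- function(join) {
  df <- dplyr::mutate(join, shared = .data$deg_a != "none" &
                        .data$deg_b != "none")
  ggplot2::ggplot(df, ggplot2::aes(.data$de_score_a, .data$de_score_b,
                                   colour = .data$shared)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey60"),
                                 labels = c(`TRUE` = "shared DEG",
                                            `FALSE` = "other")) +
    ggplot2::labs(x = "DE score (species A)", y = "DE score (species B)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
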
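#' Volcano plot of a differential-expression table
#'
#' @param object A `deg_table` from [two_group_deg()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 p, passing genes
#'   highlighted, threshold lines at the configured cutoffs.
#' @method autoplot deg_table
#' @export
autoplot.deg_table <- function(object, ...) {
  fc_min <- attr(object, "fc_min")
  p_max <- attr(object, "p_max")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log2_fc,
                                       y = -log10(.data$p_value),
                                       colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p_max),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "passes filter") +
    ggplot2::theme_minimal()
}

#' Bar chart of the top-ranked compound combinations
#'
#' @param object A `combination_ranking` from [rank_combinations()].
#' @param top_k How many combinations to show; defaults to the object's
#'   own `top_k`.
#' @param ... Unused.
#' @return A ggplot of contribution scores, best combination on top.
#' @method autoplot combination_ranking
#' @export
autoplot.combination_ranking <- function(object, top_k = NULL, ...) {
  k <- top_k %||% object$top_k
  d <- head(object$ranking, k)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score,
                                  y = stats::reorder(.data$combination, .data$score))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "contribution score", y = NULL,
                  title = sprintf("Top %d compound combinations", nrow(d))) +
    ggplot2::theme_minimal()
}

#' Heatmap of normalized knockout indicators
#'
#' @param matrix An [build_indicator_matrix()] result.
#' @param orientation Optional orientation override for normalization.
#' @return A ggplot tile map of the evaluation values (0 = least, 1 =
#'   most destabilizing per indicator).
#' @export
plot_indicator_matrix <- function(matrix, orientation = NULL) {
  z <- minmax_normalize(matrix, orientation = orientation)
  long <- tidyr::pivot_longer(as_tibble(z), -"entity_id",
                              names_to = "indicator", values_to = "z")
  ggplot2::ggplot(long, ggplot2::aes(x = toupper(.data$indicator),
                                     y = .data$entity_id, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "evaluation\nvalue") +
    ggplot2::theme_minimal()
}
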
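#' DV heatmap
#'
#' Perturbation-by-component heatmap of difference values, mirroring the
#' screen heatmaps used to eyeball which perturbations move which parts of
#' the network.
#'
#' @param object A `dv_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dv_matrix
#' @export
autoplot.dv_matrix <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$component, y = .data$perturbation,
                               fill = .data$dv)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "DV") +
    ggplot2::labs(
      x = "affected component", y = "perturbed component",
      title = paste0("Difference values",
                     if (!is.na(attr(object, "condition") %||% NA))
                       paste0(" (", attr(object, "condition"), ")") else "")
    ) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Influence-score ranking plot
#'
#' Lollipop plot of influence scores in rank order, with the most
#' influential (top 10%) set highlighted.
#'
#' @param object An `influence_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot influence_ranking
#' @export
autoplot.influence_ranking <- function(object, ...) {
  df <- tidy(object) |>
    mutate(perturbation = stats::reorder(.data$perturbation, -.data$rank))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$is, y = .data$perturbation,
                                   colour = .data$most_influential)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$is,
                                       yend = .data$perturbation),
                          linewidth = 0.3) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#D55E00"),
                                 name = "most influential") +
    ggplot2::labs(x = "influence score (sum of DVs)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Activity-level trace plot
#'
#' Per-combination mean activity levels of selected components, one point
#' per environment combination, faceted by component.
#'
#' @param table Tidy activity table.
#' @param components Components to show (default: all in the table).
#' @return A ggplot object.
#' @export
plot_activity <- function(table, components = NULL) {
  m <- mean_activity(table, components)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$env_index, y = .data$al)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~component) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "environment combination",
                  y = "activity level (replicate mean, %)") +
    ggplot2::theme_minimal(base_size = 9)
}
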
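#' Plot a count result
#'
#' Renders the counted particle mask with centroids marked, the package's
#' equivalent of the counting-mask overlay used to inspect automated
#' counts.
#'
#' @param object A `count_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot count_result
#' @export
autoplot.count_result <- function(object, ...) {
  lab <- attr(object$particles, "labels")
  df <- tibble::tibble(
    x = rep(seq_len(ncol(lab)), each = nrow(lab)),
    y = rep(seq_len(nrow(lab)), times = ncol(lab)),
    counted = as.vector(lab > 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$counted)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(
      data = tibble::as_tibble(object$particles),
      ggplot2::aes(.data$centroid_x, .data$centroid_y),
      inherit.aes = FALSE, colour = "red", shape = 3, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey15",
                                          `TRUE` = "white"),
                               guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s: %d counted, %.1f /mm2",
                      object$kind, object$count, object$density_per_mm2),
      x = "x (px)", y = "y (px)")
}

#' Plot a method comparison
#'
#' Side-by-side scatter (automated vs manual counts with the least-squares
#' line) and Bland-Altman panel (difference vs mean with bias, limits of
#' agreement, and the regression line through the differences).
#'
#' @param object A `method_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A patchwork of two ggplots.
#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(object, ...) {
  df <- tibble::tibble(mc = object$mc, ac = object$ac,
                       d = object$ac - object$mc,
                       m = (object$ac + object$mc) / 2)
  ba <- object$bland_altman
  p1 <- ggplot2::ggplot(df, ggplot2::aes(.data$mc, .data$ac)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linetype = "dotted") +
    ggplot2::labs(title = sprintf("Scatter (slope %.2f)",
                                  object$scatter_slope),
                  x = "manual count (mc)", y = "automated count (ac)")
  p2 <- ggplot2::ggplot(df, ggplot2::aes(.data$m, .data$d)) +
    ggplot2::geom_hline(yintercept = ba$mean_difference, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linetype = "dotted") +
    ggplot2::labs(title = sprintf("Bland-Altman (slope %.2f)", ba$slope),
                  x = "(ac + mc) / 2", y = "ac - mc")
  patchwork::wrap_plots(p1, p2)
}

#' Boxplots of densities by group
#'
#' The per-tissue / per-genotype density boxplot layout used to present
#' fiber and cell densities.
#'
#' @param data A tidy results tibble (e.g. from [run_batch()]).
#' @param value Column holding the density (tidy-eval).
#' @param group Grouping column, e.g. tissue or genotype (tidy-eval).
#' @param fill Optional second grouping mapped to fill (e.g. method).
#' @return A ggplot.
#' @export
plot_density_box <- function(data, value, group, fill = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes({{ group }}, {{ value }},
                                          fill = {{ fill }})) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = "events / mm2")
  p
}
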
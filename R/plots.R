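#' Transverse map of normalized cell positions with marginal densities
#'
#' Scatter of normalized positions over the idealized transverse frame with
#' the Gaussian-convolved medio-lateral and dorso-ventral marginals drawn to
#' the sides (each marginal sums to 1 over its bins).
#'
#' @param exp A normalized `pm_experiment` (or pooled pseudo-experiment).
#' @param density Optional pre-computed `pm_density` for the marginals.
#' @return A ggplot object (patchwork composition when available).
#' @export
plot_transverse_map <- function(exp, density = NULL) {
  cells <- premotor_cells(exp)
  if (is.null(density)) density <- density_matrix(exp)
  mx <- marginal(density, "x")
  my <- marginal(density, "y")
  pts <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$x_norm_um, y = .data$y_norm_um)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::coord_fixed(xlim = range(density$grid_x), ylim = range(density$grid_y)) +
    ggplot2::labs(x = "medio-lateral (um)", y = "dorso-ventral (um)",
                  title = exp$experiment_id) +
    ggplot2::theme_minimal(base_size = 9)
  top <- ggplot2::ggplot(tibble::tibble(x = mx$centres, w = mx$weights),
                         ggplot2::aes(.data$x, .data$w)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_minimal(base_size = 8)
  side <- ggplot2::ggplot(tibble::tibble(y = my$centres, w = my$weights),
                          ggplot2::aes(.data$w, .data$y)) +
    ggplot2::geom_path(colour = "#2166ac") +
    ggplot2::labs(x = "density", y = NULL) +
    ggplot2::theme_minimal(base_size = 8)
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(top, patchwork::plot_spacer(), pts, side,
                          ncol = 2, widths = c(4, 1), heights = c(1, 4))
  } else {
    pts
  }
}

#' Heatmap of a pairwise density-correlation matrix
#'
#' @param corr Symmetric correlation matrix from [correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(corr) {
  df <- tibble::as_tibble(as.data.frame(as.table(corr)),
                          .name_repair = function(x) c("row", "col", "r"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 2.4) +
    ggplot2::scale_fill_gradient(limits = c(-1, 1), low = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
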
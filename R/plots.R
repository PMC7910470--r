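#' Barcode-gap scatter plot
#'
#' Maximum intraspecific distance against the distance to the nearest
#' heterospecific neighbour, one point per species; points below the 1:1
#' line have a local barcode gap.
#'
#' @param gap_table Output of [species_gap_table()].
#' @param plot_set_only Restrict to species with `in_plot_set = TRUE`.
#' @return A ggplot object.
#' @export
plot_barcode_gap <- function(gap_table, plot_set_only = TRUE) {
  df <- gap_table |>
    dplyr::filter(!is.na(.data$max_intra_pct), !is.na(.data$nn_dist_pct))
  if (plot_set_only) df <- dplyr::filter(df, .data$in_plot_set)
  ggplot2::ggplot(df, ggplot2::aes(.data$max_intra_pct, .data$nn_dist_pct,
                                   colour = .data$gap_ok)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Maximum intraspecific K2P distance (%)",
                  y = "Nearest-neighbour K2P distance (%)",
                  colour = "Barcode gap") +
    ggplot2::theme_minimal()
}

#' Distance-distribution plot
#'
#' Violin plots of the per-species mean and maximum intraspecific
#' distances and the nearest-neighbour distances over the plotting
#' subset.
#'
#' @param gap_table Output of [species_gap_table()].
#' @return A ggplot object.
#' @export
plot_divergence <- function(gap_table) {
  df <- gap_table |>
    dplyr::filter(.data$in_plot_set) |>
    dplyr::select("species", "mean_intra_pct", "max_intra_pct",
                  "nn_dist_pct") |>
    tidyr::pivot_longer(-"species", names_to = "measure",
                        values_to = "pct") |>
    dplyr::filter(!is.na(.data$pct)) |>
    dplyr::mutate(measure = factor(
      .data$measure,
      levels = c("mean_intra_pct", "max_intra_pct", "nn_dist_pct"),
      labels = c("Mean intra", "Max intra", "Nearest neighbour")))
  ggplot2::ggplot(df, ggplot2::aes(.data$measure, .data$pct)) +
    ggplot2::geom_violin(fill = "grey85", scale = "width") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "K2P distance (%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.barcode_audit <- function(object, ...) {
  plot_barcode_gap(object$gap_table)
}
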
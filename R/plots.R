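#' Plot a sector map
#'
#' Tile map of the grid coloured by sector, in the canonical
#' core-to-transition order (sector 1 = most core-like).
#'
#' @param object A `ct_sectors`.
#' @param grid Grid table with `cell_id`, `row`, `col`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ct_sectors <- function(object, grid, ...) {
  df <- inner_join(object$cells, dplyr::select(grid, "cell_id", "row", "col"),
                   by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$sector))) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_d(name = "sector", direction = -1) +
    ggplot2::facet_wrap(~taxon) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d biogeographical sectors", object$k_general)) +
    ggplot2::theme_minimal()
}

#' Plot aspect distributions by sector
#'
#' @param aspects Cell aspect table.
#' @param sectors A `ct_sectors`.
#' @return A ggplot of the four aspect distributions per sector.
#' @export
plot_sector_aspects <- function(aspects, sectors) {
  df <- aspects |>
    inner_join(sectors$cells, by = c("cell_id", "taxon")) |>
    tidyr::pivot_longer(dplyr::all_of(aspect_cols), names_to = "aspect")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$sector), y = .data$value,
                                   fill = factor(.data$sector))) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::facet_wrap(~aspect, scales = "free_y") +
    ggplot2::labs(x = "sector (core to transition)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a GoF curve with its elbow
#'
#' @param curve Tibble with `k`, `gof` (one taxon).
#' @return A ggplot with the selected elbow marked.
#' @export
plot_gof_elbow <- function(curve) {
  k_hat <- select_k_elbow(curve)
  ggplot2::ggplot(curve, ggplot2::aes(.data$k, .data$gof)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = k_hat, linetype = 2, colour = "red") +
    ggplot2::labs(y = "goodness of fit (BSS/TSS)",
                  title = sprintf("elbow at k = %d", k_hat)) +
    ggplot2::theme_minimal()
}
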
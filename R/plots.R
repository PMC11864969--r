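#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Plot a ratio map
#'
#' Raster plot of the intensity-to-noise ratio with row 0 at the top;
#' masked pixels are blank.
#'
#' @param object A `ratio_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_map
#' @export
autoplot.ratio_map <- function(object, ...) {
  df <- tidy.ratio_map(object)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20",
                                  name = "R") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Intensity-to-noise ratio: ",
                                 object$element),
                  x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Map per-station phosphate stocks
#'
#' Simple gridded scatter of station stocks on longitude/latitude,
#' sized and coloured by areal stock.
#'
#' @param stocks Output of [station_stocks()]; must carry `latitude`
#'   and `longitude`.
#' @return A ggplot.
#' @export
plot_station_stocks <- function(stocks) {
  stopifnot(all(c("latitude", "longitude", "stock_g_m2") %in% names(stocks)))
  ggplot(stocks, aes(x = .data$longitude, y = .data$latitude,
                     colour = .data$stock_g_m2,
                     size = .data$stock_g_m2)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = expression("stock (g m"^-2*")")) +
    ggplot2::scale_size_area(guide = "none") +
    ggplot2::labs(x = "longitude (deg E)", y = "latitude (deg N)",
                  title = "Foraminiferal phosphate stock by station") +
    ggplot2::theme_minimal()
}

#' Plot per-species phosphate contents
#'
#' Dot-and-error-bar plot of species mean contents (error bars are one
#' standard deviation), on a log axis spanning the measured range.
#'
#' @param summary Output of [summarize_phosphate()] or a library-shaped
#'   tibble with `species`, `mean_content_pmol`, `sd_content_pmol`.
#' @return A ggplot.
#' @export
plot_species_contents <- function(summary) {
  stopifnot(all(c("species", "mean_content_pmol") %in% names(summary)))
  if (!("sd_content_pmol" %in% names(summary))) {
    summary$sd_content_pmol <- NA_real_
  }
  ggplot(summary,
         aes(x = stats::reorder(.data$species, .data$mean_content_pmol),
             y = .data$mean_content_pmol)) +
    ggplot2::geom_pointrange(aes(
      ymin = pmax(.data$mean_content_pmol - .data$sd_content_pmol, 0.5),
      ymax = .data$mean_content_pmol + .data$sd_content_pmol)) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = expression("phosphate content (pmol ind"^-1*")")) +
    ggplot2::theme_minimal()
}
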
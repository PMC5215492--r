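# ggplot2 helpers. Each returns the ggplot object so callers can restyle;
# plot_map() optionally writes a PNG.

#' Histogram of CSN scores
#'
#' @param scores Tibble with a `csn` column.
#' @param binwidth Histogram bin width on the \[-1, 1\] scale.
#' @return A ggplot.
#' @export
plot_csn_distribution <- function(scores, binwidth = 0.1) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$csn)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
      fill = "seagreen", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "Calculated Semantic Naturalness",
      y = "images"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of Perceived vs Calculated Semantic Naturalness
#'
#' @param paired Tibble with `csn` and `pn` columns (e.g. a report's
#'   `$paired`).
#' @return A ggplot with a least-squares guide line.
#' @export
plot_pn_vs_csn <- function(paired) {
  ggplot2::ggplot(paired, ggplot2::aes(x = .data$csn, y = .data$pn)) +
    ggplot2::geom_point(alpha = 0.7, colour = "seagreen") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      colour = "grey30", linewidth = 0.5) +
    ggplot2::labs(
      x = "Calculated Semantic Naturalness",
      y = "Perceived Naturalness (panel mean, 1-7)"
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.gv_report <- function(object, ...) {
  if (!is.null(object$paired) && "pn" %in% names(object$paired)) {
    plot_pn_vs_csn(object$paired)
  } else {
    plot_csn_distribution(object$scores)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map of sample points, panorama offsets and deprivation halos
#'
#' Draws sample points coloured by CSN (greener = more natural), joins each
#' point to its matched panorama with a segment, and — when linkage data is
#' supplied — rings the points with a halo coloured by deprivation vigintile
#' (redder = more deprived). Layers for which data is missing are simply
#' omitted.
#'
#' @param points_with_csn Tibble with `point_id`, `lon`, `lat` and `csn`.
#' @param matches Optional tibble from [match_panoramas()].
#' @param linked Optional tibble from [join_deprivation()].
#' @param out_path Optional PNG path; when given the plot is also written to
#'   disk.
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()].
#' @return The ggplot, invisibly when written to file.
#' @export
plot_map <- function(points_with_csn, matches = NULL, linked = NULL,
                     out_path = NULL, width = 7, height = 5, dpi = 150) {
  stopifnot(all(c("point_id", "lon", "lat", "csn") %in% names(points_with_csn)))
  p <- ggplot2::ggplot()
  if (!is.null(linked)) {
    halo <- dplyr::inner_join(
      points_with_csn,
      linked[linked$linked, c("point_id", "vigintile")],
      by = "point_id"
    )
    p <- p + ggplot2::geom_point(
      data = halo,
      ggplot2::aes(x = .data$lon, y = .data$lat, colour = .data$vigintile),
      size = 4, alpha = 0.6
    ) +
      ggplot2::scale_colour_gradient(
        low = "darkred", high = "grey85", name = "deprivation\nvigintile"
      )
  }
  if (!is.null(matches)) {
    seg <- dplyr::inner_join(
      points_with_csn[c("point_id", "lon", "lat")],
      matches[c("point_id", "pano_lon", "pano_lat")],
      by = "point_id"
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$pano_lon, y = .data$pano_lat,
        xend = .data$lon, yend = .data$lat
      ),
      linewidth = 0.2, colour = "grey40"
    ) +
      ggplot2::geom_point(
        data = seg,
        ggplot2::aes(x = .data$pano_lon, y = .data$pano_lat),
        size = 0.3, colour = "black"
      )
  }
  p <- p + ggplot2::geom_point(
    data = points_with_csn,
    ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$csn),
    shape = 21, size = 1.8, stroke = 0.1
  ) +
    ggplot2::scale_fill_gradient2(
      low = "firebrick", mid = "khaki", high = "darkgreen",
      midpoint = 0, limits = c(-1, 1), name = "CSN"
    ) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, p, width = width, height = height, dpi = dpi)
    return(invisible(p))
  }
  p
}
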
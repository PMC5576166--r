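#' Plot Lorenz curves for one weight basis
#'
#' One panel showing the three resource curves against the diagonal
#' equality line. On the population basis the curves of an equitable system
#' hug the diagonal; on the area basis of a sparsely settled country they
#' bow far below it.
#'
#' @param table A [region_table()].
#' @param basis `"population"` or `"area"`.
#' @return A ggplot object; use [lorenz_points()] for the plotted values.
#' @examples
#' plot_lorenz(load_mongolia_2014(), "area")
#' @export
plot_lorenz <- function(table, basis) {
  basis <- match_basis(basis)
  pts <- lorenz_points(lorenz_curves(table, basis))
  xlab <- if (basis == "population") {
    "Cumulative share of population"
  } else {
    "Cumulative share of area"
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$p, y = .data$q,
                                    colour = .data$resource)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = xlab, y = "Cumulative share of resource",
                  colour = NULL,
                  title = sprintf("Lorenz curves (%s basis)", basis)) +
    ggplot2::theme_minimal()
}

#' Per-region density pairs for the log-log scatter
#'
#' @param table A [region_table()].
#' @param resource One of [resource_kinds].
#' @param k Supply classes used for colouring (area basis).
#' @return A tibble with columns `region`, `per_10000_population`,
#'   `per_1000_km2`, `category` — the values behind
#'   [plot_density_scatter()].
#' @export
density_scatter_points <- function(table, resource, k = 4) {
  stopifnot(inherits(table, "region_table"))
  cat_tbl <- categorize_table(table, resource, "area", k = k)
  tibble::tibble(
    region = table$region,
    per_10000_population = unname(indicator_values(table, resource,
                                                   "population")),
    per_1000_km2 = unname(indicator_values(table, resource, "area")),
    category = cat_tbl$category
  )
}

#' Log-log scatter of the two density indicators
#'
#' Each region is a point at (resources per 10 000 persons, resources per
#' 1 000 km2) on base-10 logarithmic axes, coloured by its area-basis
#' supply category. Regions with a zero density cannot be log-transformed
#' and are dropped with a warning.
#'
#' @inheritParams density_scatter_points
#' @return A ggplot object; use [density_scatter_points()] for the values.
#' @examples
#' plot_density_scatter(load_mongolia_2014(), "physicians")
#' @export
plot_density_scatter <- function(table, resource, k = 4) {
  pts <- density_scatter_points(table, resource, k = k)
  zero <- pts$per_10000_population <= 0 | pts$per_1000_km2 <= 0
  if (any(zero)) {
    warning("excluding ", sum(zero),
            " region(s) with zero density from the log scatter: ",
            paste(pts$region[zero], collapse = ", "), call. = FALSE)
    pts <- pts[!zero, ]
  }
  palette <- c(red = "#c0392b", orange = "#e67e22", yellow = "#f1c40f",
               green = "#27ae60")
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$per_10000_population,
                                         y = .data$per_1000_km2,
                                         colour = .data$category)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("%s per 10 000 population", resource),
                  y = sprintf("%s per 1 000 km²", resource),
                  colour = "supply",
                  title = sprintf("Distribution of %s", resource)) +
    ggplot2::theme_minimal()
  if (all(levels(pts$category) %in% names(palette))) {
    p <- p + ggplot2::scale_colour_manual(values = palette, drop = FALSE)
  }
  p
}
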
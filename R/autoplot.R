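# ggplot2 views of the grid and series objects. All builders return a
# ggplot, so callers can restyle freely.

raster_plot_base <- function(tb, fill) {
  ggplot2::ggplot(tb[tb$valid, ], ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_fvc autoplot method.
#' @export
autoplot.rgbfvc_fvc <- function(object, ...) plot_fvc(object, ...)

#' Plot a fractional-cover map
#'
#' @param fvc An `rgbfvc_fvc` map.
#' @param object Same, for the autoplot method.
#' @param ... Unused.
#' @return A ggplot raster of cover fractions.
#' @export
plot_fvc <- function(fvc, ...) {
  raster_plot_base(as_tibble(fvc), "fvc") +
    ggplot2::scale_fill_gradient(low = "#f7efe2", high = "#1a6b2a",
                                 limits = c(0, 1), name = "FVC")
}

#' @describeIn plot_grades autoplot method.
#' @export
autoplot.rgbfvc_grades <- function(object, ...) plot_grades(object, ...)

#' Plot a cover-grade map
#'
#' @param grades An `rgbfvc_grades` map.
#' @param object Same, for the autoplot method.
#' @param ... Unused.
#' @return A ggplot raster with one discrete fill level per grade.
#' @export
plot_grades <- function(grades, ...) {
  tb <- as_tibble(grades)
  tb$grade <- factor(tb$grade, levels = grades$scheme$codes,
                     labels = grades$scheme$labels)
  raster_plot_base(tb, "grade") +
    ggplot2::scale_fill_brewer(palette = "YlGn", name = "cover grade",
                               drop = FALSE)
}

#' @describeIn plot_change autoplot method.
#' @export
autoplot.rgbfvc_change <- function(object, ...) plot_change(object, ...)

#' Plot a cover-change map
#'
#' @param change An `rgbfvc_change` map.
#' @param object Same, for the autoplot method.
#' @param ... Unused.
#' @return A ggplot raster on a diverging scale centred at zero change.
#' @export
plot_change <- function(change, ...) {
  raster_plot_base(as_tibble(change), "change") +
    ggplot2::scale_fill_gradient2(low = "#a63603", mid = "#f7f7f7",
                                  high = "#1a6b2a", limits = c(-1, 1),
                                  name = expression(Delta * "FVC"))
}

#' @describeIn plot_rgb autoplot method.
#' @export
autoplot.rgbfvc_rgb <- function(object, ...) plot_rgb(object, ...)

#' Plot an RGB image
#'
#' @param image An `rgbfvc_rgb` image (native 0-255 channels).
#' @param object Same, for the autoplot method.
#' @param ... Unused.
#' @return A ggplot true-color raster.
#' @export
plot_rgb <- function(image, ...) {
  tb <- as_tibble(image)
  tb <- tb[tb$valid, ]
  tb$col <- grDevices::rgb(pmin(pmax(tb$red, 0), 255),
                           pmin(pmax(tb$green, 0), 255),
                           pmin(pmax(tb$blue, 0), 255), maxColorValue = 255)
  ggplot2::ggplot(tb, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$col)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_series autoplot method.
#' @export
autoplot.rgbfvc_series <- function(object, ...) plot_series(object, ...)

#' Plot a multi-date mean-cover series
#'
#' @param series An `rgbfvc_series` from [series_summary()].
#' @param object Same, for the autoplot method.
#' @param ... Unused.
#' @return A ggplot line chart of mean FVC against date.
#' @export
plot_series <- function(series, ...) {
  tb <- tibble(date = factor(series$date, levels = series$date),
               mean_fvc = series$mean_fvc)
  ggplot2::ggplot(tb, ggplot2::aes(.data$date, .data$mean_fvc, group = 1)) +
    ggplot2::geom_line(color = "#1a6b2a") +
    ggplot2::geom_point(color = "#1a6b2a") +
    ggplot2::scale_y_continuous(limits = c(0, 1), name = "mean FVC") +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal()
}
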
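# ggplot2 graphics for spectra, Lab clouds and reports.

#' Plot spectra
#'
#' @param ... Named `hs_spectrum` objects (names become the legend).
#' @return A ggplot.
#' @export
plot_spectra <- function(...) {
  specs <- list(...)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- paste0("spectrum", seq_along(specs))
  }
  df <- purrr::imap_dfr(specs, function(s, nm) {
    tibble::tibble(series = nm, wavelength = s$wavelength, value = s$value)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "value", color = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hs_spectrum <- function(object, ...) {
  plot_spectra(spectrum = object)
}

#' Plot a CIELAB pixel cloud in the a*-b* plane
#'
#' @param lab Tibble with `L`, `a`, `b` (e.g. from [cube_to_lab()]); an
#'   optional `group` column colors the points.
#' @return A ggplot.
#' @export
plot_lab_cloud <- function(lab) {
  p <- ggplot2::ggplot(lab, ggplot2::aes(.data$a, .data$b))
  if ("group" %in% names(lab)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$group),
                                 alpha = 0.4, size = 0.5)
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$L),
                                 alpha = 0.4, size = 0.5)
  }
  p + ggplot2::labs(x = "a*", y = "b*") + ggplot2::theme_minimal()
}

#' Display an sRGB rendering or a difference map
#'
#' @param img rows x cols x 3 sRGB array from [render_srgb()], or a numeric
#'   matrix (rendered as a grayscale-to-viridis heat map).
#' @return A ggplot.
#' @export
plot_image <- function(img) {
  if (length(dim(img)) == 3) {
    d <- dim(img)
    df <- tibble::tibble(
      row = rep(seq_len(d[1]), times = d[2]),
      col = rep(seq_len(d[2]), each = d[1]),
      fill = grDevices::rgb(img[, , 1], img[, , 2], img[, , 3],
                            maxColorValue = 255)
    )
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$fill)) +
      ggplot2::geom_raster() + ggplot2::scale_fill_identity() +
      ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
      ggplot2::theme_void()
  } else {
    df <- tibble::tibble(
      row = rep(seq_len(nrow(img)), times = ncol(img)),
      col = rep(seq_len(ncol(img)), each = nrow(img)),
      value = as.vector(img)
    )
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
      ggplot2::geom_raster() + ggplot2::scale_fill_viridis_c() +
      ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
      ggplot2::theme_void()
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.skin_group_stats <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.9), width = 0.2) +
    ggplot2::labs(x = NULL, y = "CIELAB value", fill = "group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
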
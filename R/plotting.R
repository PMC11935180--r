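#' 'jet' color palette
#'
#' The classic blue-cyan-yellow-red map used for pressure/dose displays.
#'
#' @param n number of colors.
#' @return Character vector of colors.
#' @export
jet_colors <- function(n = 256L) {
  grDevices::colorRampPalette(c("#00007F", "blue", "#007FFF", "cyan",
                                "#7FFF7F", "yellow", "#FF7F00", "red",
                                "#7F0000"))(n)
}

#' Display a pressure map with the jet palette
#'
#' @param values numeric matrix (row 1 drawn at the top).
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot_pressure_map <- function(values, main = "", ...) {
  check_matrix(values)
  m <- t(values[nrow(values):1, , drop = FALSE])
  graphics::image(m, col = jet_colors(), axes = FALSE, main = main,
                  useRaster = TRUE, asp = ncol(values) / nrow(values), ...)
  invisible(values)
}

#' Export a pressure map as a jet-colormapped PNG
#'
#' Intensities are min-max normalized before color mapping. Requires the
#' `png` package.
#'
#' @param values numeric matrix.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
save_image_png <- function(values, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' is required for PNG export", call. = FALSE)
  check_matrix(values)
  v <- normalize01(values, on_constant = "zero")
  pal <- grDevices::col2rgb(jet_colors(256L)) / 255
  idx <- pmin(255L, pmax(0L, as.integer(round(v * 255)))) + 1L
  rgb <- array(0, c(nrow(v), ncol(v), 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[ch, idx], nrow(v), ncol(v))
  png::writePNG(rgb, path)
  invisible(path)
}
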
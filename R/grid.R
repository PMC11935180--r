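#' Define the reconstruction image grid
#'
#' The grid fixes the spatial frame shared by phantoms, the acoustic forward
#' model and all reconstructions. Coordinates are in millimetres; world x runs
#' along columns and world y along rows; voxel centers are the reference
#' points (row-major, 0-based in the C++ kernels). By default the grid is
#' centered on the world origin and the rotation center coincides with the
#' grid's geometric center.
#'
#' @param n_rows,n_cols voxel counts (>= 8).
#' @param spacing voxel edge length in mm (> 0).
#' @param origin world coordinate `c(x, y)` of the center of voxel (1, 1),
#'   in mm. Default centers the grid at (0, 0).
#' @param rotation_center world coordinate `c(x, y)` about which views are
#'   rotated. Defaults to the grid's geometric center.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(n_rows = 256L, n_cols = 256L, spacing = 0.15,
                       origin = NULL, rotation_center = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 8L || n_cols < 8L)
    stop("grid must be at least 8x8 voxels", call. = FALSE)
  stopifnot_scalar_num(spacing, "spacing", positive = TRUE)
  if (is.null(origin))
    origin <- c(-(n_cols - 1) / 2 * spacing, -(n_rows - 1) / 2 * spacing)
  origin <- as.numeric(origin)
  if (length(origin) != 2L) stop("`origin` must be c(x, y)", call. = FALSE)
  center <- origin + c((n_cols - 1) / 2, (n_rows - 1) / 2) * spacing
  rotation_center <- as.numeric(rotation_center %||% center)
  if (length(rotation_center) != 2L)
    stop("`rotation_center` must be c(x, y)", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 origin = origin, rotation_center = rotation_center),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d voxels, %.4g mm spacing\n",
              x$n_rows, x$n_cols, x$spacing))
  cat(sprintf("  origin (%.3g, %.3g) mm; rotation center (%.3g, %.3g) mm\n",
              x$origin[1], x$origin[2],
              x$rotation_center[1], x$rotation_center[2]))
  invisible(x)
}

# rotation center in 0-based (row, col) pixel units
grid_center_px <- function(grid) {
  c(row = (grid$rotation_center[2] - grid$origin[2]) / grid$spacing,
    col = (grid$rotation_center[1] - grid$origin[1]) / grid$spacing)
}

# world extent covered by voxel centers: list(x = c(lo, hi), y = c(lo, hi))
grid_extent <- function(grid) {
  list(x = c(grid$origin[1], grid$origin[1] + (grid$n_cols - 1) * grid$spacing),
       y = c(grid$origin[2], grid$origin[2] + (grid$n_rows - 1) * grid$spacing))
}

#' Rotate an image about the grid's rotation center
#'
#' Bilinear interpolation, zero fill outside the grid. Positive angles rotate
#' counter-clockwise in the (x, y) world frame. `rotate_image_adjoint()` is
#' the exact matrix transpose of `rotate_image()` at the same angle; it is
#' what the adjoint acoustic operator uses so that forward/adjoint pairs pass
#' dot-product tests to machine precision.
#'
#' @param values numeric matrix on `grid`.
#' @param angle rotation angle in degrees.
#' @param grid an [image_grid()].
#' @return Rotated matrix of the same dimensions.
#' @export
rotate_image <- function(values, angle, grid) {
  check_matrix(values)
  ctr <- grid_center_px(grid)
  cpp_rotate_bilinear(values, angle, ctr["row"], ctr["col"])
}

#' @rdname rotate_image
#' @export
rotate_image_adjoint <- function(values, angle, grid) {
  check_matrix(values)
  ctr <- grid_center_px(grid)
  cpp_rotate_adjoint(values, angle, ctr["row"], ctr["col"])
}

# normalized 1-D Gaussian kernel, scipy-style truncation
gauss_kernel <- function(sigma, truncate = 3.5) {
  r <- floor(truncate * sigma + 0.5)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# separable Gaussian blur, zero padding (sigma in pixels)
gauss_blur <- function(values, sigma_px) {
  if (sigma_px <= 0) return(values)
  cpp_sepconv_same(values, gauss_kernel(sigma_px))
}
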
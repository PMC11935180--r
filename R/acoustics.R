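#' Linear-array geometry and acquisition parameters
#'
#' Mirrors the acquisition chain: a 128-channel linear-array ultrasound
#' probe sampled at 40 MHz with 12-bit digitization. The array face is a
#' straight line parallel to the world x axis, centered laterally on the
#' grid's rotation center at perpendicular distance `standoff`.
#'
#' @param n_elements number of transducer elements (default 128).
#' @param pitch element center-to-center spacing in mm. Default 60/128 mm
#'   (a 60 mm aperture probe).
#' @param standoff perpendicular distance from the array face to the
#'   rotation center, mm (default 40).
#' @param sound_speed speed of sound in m/s (default 1480, water at room
#'   temperature).
#' @param sampling_rate samples per second (default 40e6).
#' @param n_samples time samples per channel; `NULL` means derive the
#'   minimum record that holds the farthest voxel's time of flight plus 8
#'   guard samples (see [required_samples()]).
#' @param quantization_bits optional DAQ bit depth (e.g. 12); `NULL`
#'   disables quantization.
#' @param time_filter apply a first-difference filter along time to
#'   approximate the derivative character of acoustic transients. Default
#'   `FALSE`, keeping the operator exactly linear and matched to its
#'   adjoint.
#' @return An object of class `array_geometry`.
#' @export
array_geometry <- function(n_elements = 128L, pitch = 60 / 128,
                           standoff = 40, sound_speed = 1480,
                           sampling_rate = 40e6, n_samples = NULL,
                           quantization_bits = NULL, time_filter = FALSE) {
  n_elements <- as.integer(n_elements)
  if (n_elements < 2L) stop("`n_elements` must be >= 2", call. = FALSE)
  stopifnot_scalar_num(pitch, "pitch", positive = TRUE)
  stopifnot_scalar_num(standoff, "standoff", positive = TRUE)
  stopifnot_scalar_num(sound_speed, "sound_speed", positive = TRUE)
  stopifnot_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  if (!is.null(n_samples)) {
    n_samples <- as.integer(n_samples)
    if (n_samples < 2L) stop("`n_samples` must be >= 2", call. = FALSE)
  }
  if (!is.null(quantization_bits)) {
    quantization_bits <- as.integer(quantization_bits)
    if (quantization_bits < 2L)
      stop("`quantization_bits` must be >= 2", call. = FALSE)
  }
  structure(list(n_elements = n_elements, pitch = pitch, standoff = standoff,
                 sound_speed = sound_speed, sampling_rate = sampling_rate,
                 n_samples = n_samples, quantization_bits = quantization_bits,
                 time_filter = isTRUE(time_filter)),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "<array_geometry> %d elements, pitch %.4g mm, standoff %g mm\n",
    x$n_elements, x$pitch, x$standoff))
  cat(sprintf("  c = %g m/s, fs = %g MHz%s%s\n", x$sound_speed,
              x$sampling_rate / 1e6,
              if (is.null(x$quantization_bits)) "" else
                sprintf(", %d-bit DAQ", x$quantization_bits),
              if (x$time_filter) ", first-difference filter" else ""))
  invisible(x)
}

#' Element center positions in the world frame
#'
#' @param geometry an [array_geometry()].
#' @param grid an [image_grid()]; the array is placed relative to its
#'   rotation center.
#' @return `n_elements` x 2 matrix of `(x, y)` positions in mm; the lateral
#'   midpoint of the row equals the rotation center's x coordinate.
#' @export
element_positions <- function(geometry, grid) {
  rc <- grid$rotation_center
  i <- seq_len(geometry$n_elements)
  x <- rc[1] + (i - (geometry$n_elements + 1) / 2) * geometry$pitch
  y <- rep(rc[2] - geometry$standoff, geometry$n_elements)
  cbind(x = x, y = y)
}

#' Minimal time-record length for a grid/geometry pairing
#'
#' The farthest voxel-to-element time of flight in samples, plus 8 guard
#' samples (rotation about the rotation center cannot move content outside
#' the grid's corner radius, so the bound holds for every view).
#'
#' @inheritParams element_positions
#' @return Integer number of samples.
#' @export
required_samples <- function(geometry, grid) {
  ext <- grid_extent(grid)
  corners <- expand.grid(x = ext$x, y = ext$y)
  pos <- element_positions(geometry, grid)
  dmax <- 0
  for (k in seq_len(nrow(corners))) {
    d <- sqrt((corners$x[k] - pos[, 1])^2 + (corners$y[k] - pos[, 2])^2)
    dmax <- max(dmax, d)
  }
  as.integer(ceiling(dmax * 1e-3 / geometry$sound_speed *
                       geometry$sampling_rate)) + 8L
}

resolve_n_samples <- function(geometry, grid) {
  need <- required_samples(geometry, grid)
  n <- geometry$n_samples %||% need
  if (n < need)
    stop(sprintf(paste0("time record too short: the farthest voxel's ",
                        "time of flight needs n_samples >= %d (got %d)"),
                 need, n), call. = FALSE)
  as.integer(n)
}

first_difference <- function(values) {
  cbind(values[, 1, drop = FALSE],
        values[, -1, drop = FALSE] - values[, -ncol(values), drop = FALSE])
}

quantize_signal <- function(values, bits) {
  full_scale <- max(abs(values))
  if (full_scale == 0) return(values)
  step <- full_scale / 2^(bits - 1)
  round(values / step) * step
}

#' Simulate linear-array channel data for one view
#'
#' The forward model of the acquisition: the source map is rotated by
#' `-view_angle` about the rotation center (the electrodes rotate, the array
#' stays fixed), then each voxel's amplitude is spread into the time bins
#' adjacent to its time of flight to each element (linear bin splitting)
#' with spherical-spreading weight `1 / max(distance, spacing)`. With
#' `time_filter` and `quantization_bits` off the operator is exactly linear
#' in the source and exactly matched to [adjoint_channels()].
#'
#' @param source a [pressure_source_map()].
#' @param geometry an [array_geometry()].
#' @param view_angle view angle in degrees, in `[0, 360)`.
#' @return An object of class `channel_gram` with fields `values`
#'   (`n_elements` x `n_samples`), `view_angle` and `geometry`.
#' @export
simulate_channels <- function(source, geometry, view_angle = 0) {
  if (!inherits(source, "pressure_source_map"))
    stop("`source` must be a pressure_source_map", call. = FALSE)
  if (view_angle < 0 || view_angle >= 360)
    stop("`view_angle` must be in [0, 360)", call. = FALSE)
  grid <- source$grid
  n_samples <- resolve_n_samples(geometry, grid)
  rot <- rotate_image(source$values, -view_angle, grid)
  pos <- element_positions(geometry, grid)
  g <- cpp_forward_project(rot, pos[, 1], pos[, 2],
                           grid$origin[1], grid$origin[2], grid$spacing,
                           geometry$sampling_rate, geometry$sound_speed,
                           n_samples)
  if (geometry$time_filter) g <- first_difference(g)
  if (!is.null(geometry$quantization_bits))
    g <- quantize_signal(g, geometry$quantization_bits)
  channel_gram(g, view_angle, geometry)
}

#' @rdname simulate_channels
#' @param values `n_elements` x `n_samples` numeric matrix.
#' @export
channel_gram <- function(values, view_angle, geometry) {
  check_matrix(values)
  if (nrow(values) != geometry$n_elements)
    stop("gram rows must equal n_elements", call. = FALSE)
  if (view_angle < 0 || view_angle >= 360)
    stop("`view_angle` must be in [0, 360)", call. = FALSE)
  structure(list(values = values, view_angle = view_angle,
                 geometry = geometry), class = "channel_gram")
}

#' @export
print.channel_gram <- function(x, ...) {
  cat(sprintf("<channel_gram> %d elements x %d samples, view %g deg\n",
              nrow(x$values), ncol(x$values), x$view_angle))
  invisible(x)
}

#' Exact adjoint of the linear forward operator
#'
#' Spreads each time bin's value back to the voxels that contributed to it,
#' with the same `1 / max(d, spacing)` weights and linear bin splitting,
#' followed by the transpose of the forward view rotation. Together with
#' [simulate_channels()] (filter and quantization off) this passes a
#' dot-product test to machine precision; it is the core of
#' [backproject()].
#'
#' @param gram a [channel_gram()].
#' @param grid the [image_grid()] of the source.
#' @return A [pressure_source_map()]-shaped object of class
#'   `pressure_source_map` (values may be any sign-free adjoint output, so
#'   negativity checks are skipped here).
#' @export
adjoint_channels <- function(gram, grid) {
  if (!inherits(gram, "channel_gram"))
    stop("`gram` must be a channel_gram", call. = FALSE)
  core <- adjoint_core(gram, grid)
  out <- rotate_image_adjoint(core, -gram$view_angle, grid)
  structure(list(values = out, grid = grid), class = "pressure_source_map")
}

# back-smearing into the array frame, no rotation
adjoint_core <- function(gram, grid) {
  geometry <- gram$geometry
  n_samples <- ncol(gram$values)
  need <- required_samples(geometry, grid)
  if (n_samples < need)
    stop(sprintf("gram record length %d shorter than required %d",
                 n_samples, need), call. = FALSE)
  pos <- element_positions(geometry, grid)
  cpp_adjoint_project(gram$values, pos[, 1], pos[, 2],
                      grid$origin[1], grid$origin[2], grid$spacing,
                      geometry$sampling_rate, geometry$sound_speed,
                      grid$n_rows, grid$n_cols)
}
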
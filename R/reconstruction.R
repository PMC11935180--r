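#' Delay-and-sum back-projection of one view
#'
#' For each voxel, sums over elements the channel value at the voxel's time
#' of flight (linear interpolation between time bins), weighted by
#' `1 / max(d, spacing)`, normalized by the element count. With the time
#' filter off this equals the adjoint operator's back-smearing up to that
#' normalization. The image stays in the array's frame and carries the
#' gram's `view_angle`; de-rotation into the common object frame happens in
#' [composite_full_view()]. Negative values are kept; normalization to
#' \[0, 1\] happens only in metrics/training.
#'
#' @param gram a [channel_gram()].
#' @param grid the reconstruction [image_grid()].
#' @return An object of class `single_view_image` with fields `values`,
#'   `view_angle` and `grid`.
#' @export
backproject <- function(gram, grid) {
  if (!inherits(gram, "channel_gram"))
    stop("`gram` must be a channel_gram", call. = FALSE)
  if (!inherits(grid, "image_grid"))
    stop("`grid` must be an image_grid", call. = FALSE)
  g <- gram
  if (gram$geometry$time_filter)
    g <- channel_gram(first_difference(gram$values), gram$view_angle,
                      gram$geometry)
  values <- adjoint_core(g, grid) / gram$geometry$n_elements
  single_view_image(values, gram$view_angle, grid)
}

#' @rdname backproject
#' @param values numeric matrix matching `grid`.
#' @param view_angle view angle in degrees.
#' @export
single_view_image <- function(values, view_angle, grid) {
  check_matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("image dimensions do not match the grid", call. = FALSE)
  structure(list(values = values, view_angle = view_angle, grid = grid),
            class = "single_view_image")
}

#' @export
print.single_view_image <- function(x, ...) {
  cat(sprintf("<single_view_image> %d x %d, view %g deg\n",
              nrow(x$values), ncol(x$values), x$view_angle))
  invisible(x)
}

#' Composite full-view image from de-rotated single views
#'
#' Rotates each single-view image by `+view_angle` about the rotation
#' center (back into the common object frame) and returns the voxelwise
#' arithmetic mean. This is the ground-truth construction: the full-view
#' image against which single-view reconstructions and their enhanced
#' versions are compared.
#'
#' @param singles non-empty list of `single_view_image`s sharing one grid,
#'   with distinct view angles.
#' @param grid the shared [image_grid()].
#' @return An object of class `full_view_image` with fields `values`,
#'   `n_views` and `grid`.
#' @export
composite_full_view <- function(singles, grid) {
  if (length(singles) == 0L)
    stop("`singles` must be a non-empty list of views", call. = FALSE)
  angs <- vapply(singles, function(s) s$view_angle, numeric(1))
  if (anyDuplicated(angs))
    stop("view angles must be distinct", call. = FALSE)
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  for (s in singles) {
    if (!inherits(s, "single_view_image"))
      stop("all elements must be single_view_image objects", call. = FALSE)
    if (nrow(s$values) != grid$n_rows || ncol(s$values) != grid$n_cols)
      stop("all views must share the same grid", call. = FALSE)
    acc <- acc + rotate_image(s$values, s$view_angle, grid)
  }
  structure(list(values = acc / length(singles), n_views = length(singles),
                 grid = grid), class = "full_view_image")
}

#' @export
print.full_view_image <- function(x, ...) {
  cat(sprintf("<full_view_image> %d x %d, %d views\n",
              nrow(x$values), ncol(x$values), x$n_views))
  invisible(x)
}

#' Build the complete view set for one electrode configuration
#'
#' Generates the phantom, simulates the channel data for `n_views` equally
#' distributed views over 360 degrees (angles 0, 360/n, 2*360/n, ...),
#' back-projects each view, and composites the full-view image. Fully
#' deterministic given its inputs.
#'
#' @param config an [electrode_config()].
#' @param geometry an [array_geometry()].
#' @param grid an [image_grid()].
#' @param n_views number of views (default 60, i.e. 6 degree steps).
#' @param dataset_id identifier string recorded in the result.
#' @return An object of class `viewset` with fields `dataset_id`, `config`,
#'   `source`, `grams`, `singles`, `full` and `angles`.
#' @export
build_viewset <- function(config, geometry, grid, n_views = 60L,
                          dataset_id = "dataset") {
  n_views <- as.integer(n_views)
  if (n_views < 1L) stop("`n_views` must be >= 1", call. = FALSE)
  source <- generate_phantom(config, grid)
  angles <- (seq_len(n_views) - 1) * 360 / n_views
  grams <- lapply(angles, function(a) simulate_channels(source, geometry, a))
  singles <- lapply(grams, backproject, grid = grid)
  full <- composite_full_view(singles, grid)
  structure(list(dataset_id = dataset_id, config = config, source = source,
                 grams = grams, singles = singles, full = full,
                 angles = angles), class = "viewset")
}

#' @export
print.viewset <- function(x, ...) {
  cat(sprintf("<viewset> '%s': %d views over 360 deg, grid %d x %d\n",
              x$dataset_id, length(x$grams),
              x$full$grid$n_rows, x$full$grid$n_cols))
  invisible(x)
}
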
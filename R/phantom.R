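#' Two-electrode nsPEF energy-deposition phantom configuration
#'
#' Describes one electrode arrangement: two tungsten electrode tips inside
#' the field of view, a field-intensity scale in V/cm, a Gaussian tip
#' smoothing width, and an optional echo-artifact amplitude. Phantoms stand
#' in for the energy absorbed around an electrode pair during a nanosecond
#' pulsed electric field (nsPEF) exposure.
#'
#' @param tip_a,tip_b world positions `c(x, y)` in mm of the two electrode
#'   tips; must be distinct and strictly inside the grid.
#' @param voltage field-intensity scale in V/cm (>= 0; the deposited energy
#'   scales with `voltage^2`, so 0 yields an all-zero map).
#' @param tip_sigma Gaussian tip-smoothing width in mm (> 0). Default 0.8 mm
#'   so tips occupy a few voxels at the default grid spacing.
#' @param echo_amplitude fraction in \[0, 1\] of the peak used for the
#'   additive echo nuisance term (two blobs on the tip axis beyond the tips,
#'   emulating echoes between electrodes). 0 disables it.
#' @param seed optional integer identity for configs drawn by
#'   [sample_config()]; unused by [generate_phantom()], which is
#'   deterministic.
#' @return An object of class `electrode_config`.
#' @export
electrode_config <- function(tip_a, tip_b, voltage, tip_sigma = 0.8,
                             echo_amplitude = 0, seed = NULL) {
  tip_a <- as.numeric(tip_a); tip_b <- as.numeric(tip_b)
  if (length(tip_a) != 2L || length(tip_b) != 2L)
    stop("electrode tips must be c(x, y) in mm", call. = FALSE)
  if (all(tip_a == tip_b))
    stop("electrode tips must be distinct", call. = FALSE)
  stopifnot_scalar_num(voltage, "voltage")
  if (voltage < 0) stop("`voltage` must be >= 0", call. = FALSE)
  stopifnot_scalar_num(tip_sigma, "tip_sigma", positive = TRUE)
  stopifnot_scalar_num(echo_amplitude, "echo_amplitude")
  if (echo_amplitude < 0 || echo_amplitude > 1)
    stop("`echo_amplitude` must be in [0, 1]", call. = FALSE)
  structure(list(tip_a = tip_a, tip_b = tip_b, voltage = voltage,
                 tip_sigma = tip_sigma, echo_amplitude = echo_amplitude,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "electrode_config")
}

#' @export
print.electrode_config <- function(x, ...) {
  cat(sprintf(
    "<electrode_config> tips (%.2f, %.2f) / (%.2f, %.2f) mm, %g V/cm\n",
    x$tip_a[1], x$tip_a[2], x$tip_b[1], x$tip_b[2], x$voltage))
  cat(sprintf("  tip_sigma %.3g mm, echo_amplitude %.3g%s\n",
              x$tip_sigma, x$echo_amplitude,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Generate a synthetic energy-deposition map for an electrode pair
#'
#' Evaluates a two-point-charge log-potential dipole field (+1 at `tip_a`,
#' -1 at `tip_b`, distances clamped below by `tip_sigma`), takes the energy
#' density `voltage^2 * |grad phi|^2`, smooths it with a Gaussian of width
#' `tip_sigma`, clips the tip singularities at the `clip_percentile`-th
#' percentile and rescales so the peak equals `voltage^2` (arbitrary
#' pressure units; the proportionality constant is 1 since all downstream
#' metrics work on \[0, 1\]-normalized images). With `echo_amplitude > 0`,
#' two Gaussian blobs of that fraction of the peak are added on the tip-tip
#' axis beyond each tip as an echo-artifact nuisance term. Deterministic
#' given `(config, grid)`.
#'
#' @param config an [electrode_config()].
#' @param grid an [image_grid()].
#' @param clip_percentile percentile (0-100) at which the dipole
#'   singularities are clipped before rescaling. Default 99.5.
#' @return An object of class `pressure_source_map` with fields `values`
#'   (non-negative matrix) and `grid`.
#' @export
generate_phantom <- function(config, grid, clip_percentile = 99.5) {
  if (!inherits(config, "electrode_config"))
    stop("`config` must be an electrode_config", call. = FALSE)
  if (!inherits(grid, "image_grid"))
    stop("`grid` must be an image_grid", call. = FALSE)
  ext <- grid_extent(grid)
  inside <- function(p) p[1] > ext$x[1] && p[1] < ext$x[2] &&
    p[2] > ext$y[1] && p[2] < ext$y[2]
  if (!inside(config$tip_a) || !inside(config$tip_b))
    stop("electrode tips must lie strictly inside the field of view",
         call. = FALSE)

  if (config$voltage == 0)
    return(pressure_source_map(matrix(0, grid$n_rows, grid$n_cols), grid))

  xs <- grid$origin[1] + (seq_len(grid$n_cols) - 1) * grid$spacing
  ys <- grid$origin[2] + (seq_len(grid$n_rows) - 1) * grid$spacing
  X <- matrix(xs, grid$n_rows, grid$n_cols, byrow = TRUE)
  Y <- matrix(ys, grid$n_rows, grid$n_cols)

  s2 <- config$tip_sigma^2
  grad_term <- function(tip, sign) {
    dx <- X - tip[1]; dy <- Y - tip[2]
    d2 <- pmax(dx * dx + dy * dy, s2)
    list(gx = sign * dx / d2, gy = sign * dy / d2)
  }
  ga <- grad_term(config$tip_a, +1)
  gb <- grad_term(config$tip_b, -1)
  gx <- ga$gx + gb$gx
  gy <- ga$gy + gb$gy
  w <- config$voltage^2 * (gx * gx + gy * gy)

  w <- gauss_blur(w, config$tip_sigma / grid$spacing)
  w <- pmax(w, 0)
  q <- stats::quantile(w, clip_percentile / 100, names = FALSE)
  w <- pmin(w, q)
  peak <- max(w)
  if (peak > 0) w <- w / peak * config$voltage^2

  if (config$echo_amplitude > 0) {
    u <- config$tip_b - config$tip_a
    L <- sqrt(sum(u * u)); u <- u / L
    amp <- config$echo_amplitude * config$voltage^2
    for (ctr in list(config$tip_a - 0.5 * L * u,
                     config$tip_b + 0.5 * L * u)) {
      d2b <- (X - ctr[1])^2 + (Y - ctr[2])^2
      w <- w + amp * exp(-d2b / (2 * s2))
    }
  }
  pressure_source_map(w, grid)
}

#' @rdname generate_phantom
#' @param values non-negative numeric matrix matching `grid`.
#' @export
pressure_source_map <- function(values, grid) {
  check_matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("map dimensions do not match the grid", call. = FALSE)
  if (any(values < 0))
    stop("pressure source values must be non-negative", call. = FALSE)
  structure(list(values = values, grid = grid), class = "pressure_source_map")
}

#' @export
print.pressure_source_map <- function(x, ...) {
  cat(sprintf("<pressure_source_map> %d x %d, peak %.4g\n",
              nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

#' Draw a random electrode configuration
#'
#' Samples tip separation, midpoint, axis angle, voltage and echo amplitude
#' uniformly from stated bounds to emulate the variety of electrode
#' arrangements (distances and angles relative to the array) used to build
#' the training corpus. Identical seeds give identical configurations; the
#' caller's RNG state is left untouched.
#'
#' @param rng_seed integer seed identifying the configuration.
#' @param voltage_range interval `c(lo, hi)` of field intensities in V/cm;
#'   both ends > 0, `lo <= hi`.
#' @param grid an [image_grid()]; sampling bounds scale with its extent.
#' @param tip_sigma tip smoothing width in mm passed through.
#' @param echo_range interval for the echo-artifact amplitude fraction.
#' @param separation_frac,center_frac tip separation range and midpoint
#'   offset bound, as fractions of the smaller field-of-view extent.
#' @return An [electrode_config()].
#' @export
sample_config <- function(rng_seed, voltage_range, grid, tip_sigma = 0.8,
                          echo_range = c(0.05, 0.25),
                          separation_frac = c(0.15, 0.35),
                          center_frac = 0.15) {
  voltage_range <- as.numeric(voltage_range)
  if (length(voltage_range) != 2L || any(!is.finite(voltage_range)) ||
      voltage_range[1] <= 0 || voltage_range[1] > voltage_range[2])
    stop("`voltage_range` must be c(lo, hi) with 0 < lo <= hi", call. = FALSE)
  ext <- grid_extent(grid)
  fov <- min(diff(ext$x), diff(ext$y))
  center <- c(mean(ext$x), mean(ext$y))
  with_seed(rng_seed, {
    sep <- runif(1, separation_frac[1], separation_frac[2]) * fov
    mid <- center + runif(2, -center_frac, center_frac) * fov
    ang <- runif(1, 0, 360) * pi / 180
    u <- c(cos(ang), sin(ang))
    voltage <- runif(1, voltage_range[1], voltage_range[2])
    echo <- runif(1, echo_range[1], echo_range[2])
    electrode_config(tip_a = mid - sep / 2 * u, tip_b = mid + sep / 2 * u,
                     voltage = voltage, tip_sigma = tip_sigma,
                     echo_amplitude = echo, seed = rng_seed)
  })
}
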
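# Shared fixtures: a small grid/array pairing sized for second-scale tests,
# random-image helpers, and an external SSIM oracle (scikit-image via the
# system python), used to cross-check the package's own implementation.

tiny_grid <- function(n = 32L, spacing = 1) image_grid(n, n, spacing = spacing)

tiny_geometry <- function(n_elements = 16L, pitch = 3, standoff = 40)
  array_geometry(n_elements = n_elements, pitch = pitch, standoff = standoff)

rand_image <- function(n = 64L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n * n), n, n)
}

centered_config <- function(voltage = 1500, sep = 10, echo = 0,
                            tip_sigma = 1.2) {
  electrode_config(c(-sep / 2, 0), c(sep / 2, 0), voltage,
                   tip_sigma = tip_sigma, echo_amplitude = echo)
}

# ring phantom: rotationally symmetric about the grid center; defaults keep
# the ring compact (3 sigma inside the grid, so rotations clip no mass) and
# well sampled (sigma ~ 3 voxels, so bilinear rotation errors stay ~1%)
ring_phantom <- function(grid, radius_frac = 0.22, width_frac = 0.09) {
  xs <- grid$origin[1] + (seq_len(grid$n_cols) - 1) * grid$spacing
  ys <- grid$origin[2] + (seq_len(grid$n_rows) - 1) * grid$spacing
  X <- matrix(xs, grid$n_rows, grid$n_cols, byrow = TRUE)
  Y <- matrix(ys, grid$n_rows, grid$n_cols)
  ext <- c(diff(range(xs)), diff(range(ys)))
  r <- sqrt((X - grid$rotation_center[1])^2 + (Y - grid$rotation_center[2])^2)
  r0 <- radius_frac * min(ext); w <- width_frac * min(ext)
  pressure_source_map(exp(-(r - r0)^2 / (2 * w^2)), grid)
}

# reference SSIM from scikit-image (Wang et al. constants, gaussian window)
skimage_ssim <- function(a, b) {
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fa, fb)), add = TRUE)
  utils::write.table(a, fa, row.names = FALSE, col.names = FALSE, sep = ",")
  utils::write.table(b, fb, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- paste0(
    "import numpy as np; from skimage.metrics import structural_similarity as s; ",
    sprintf("a=np.loadtxt('%s',delimiter=','); b=np.loadtxt('%s',delimiter=','); ",
            fa, fb),
    "print('%.15f' % s(a,b,gaussian_weights=True,sigma=1.5,",
    "use_sample_covariance=False,data_range=1.0))")
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  as.numeric(out[length(out)])
}

# build the dense matrix of the linear forward operator on a small instance
# by pushing unit vectors through the public API (the brute-force oracle for
# adjointness checks)
dense_forward_matrix <- function(grid, geometry, view_angle) {
  n_vox <- grid$n_rows * grid$n_cols
  probe <- simulate_channels(
    pressure_source_map(matrix(0, grid$n_rows, grid$n_cols) + 0, grid),
    geometry, view_angle)
  m <- length(probe$values)
  A <- matrix(0, m, n_vox)
  for (j in seq_len(n_vox)) {
    e <- matrix(0, grid$n_rows, grid$n_cols); e[j] <- 1
    A[, j] <- as.vector(
      simulate_channels(pressure_source_map(e, grid), geometry,
                        view_angle)$values)
  }
  A
}
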
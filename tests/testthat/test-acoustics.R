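test_that("element positions form a centered line with the stated pitch", {
  g <- tiny_grid()
  geo <- tiny_geometry(n_elements = 2, pitch = 1)
  pos <- element_positions(geo, g)
  expect_equal(nrow(pos), 2)
  expect_equal(sqrt(sum((pos[1, ] - pos[2, ])^2)), 1)

  geo128 <- array_geometry()  # default probe: 128 channels
  pos128 <- element_positions(geo128, g)
  expect_equal(nrow(pos128), 128)
  # lateral midpoint equals the rotation center's x; constant standoff in y
  expect_equal(mean(pos128[, 1]), g$rotation_center[1])
  expect_equal(unique(pos128[, 2]), g$rotation_center[2] - geo128$standoff)
  expect_equal(diff(pos128[, 1]), rep(geo128$pitch, 127))
})

test_that("a single voxel lands in the two bins adjacent to its time of flight", {
  g <- tiny_grid(32, spacing = 1)
  geo <- tiny_geometry(n_elements = 4, pitch = 6)
  src <- matrix(0, 32, 32); src[10, 17] <- 2.5
  gram <- simulate_channels(pressure_source_map(src, g), geo, 0)
  pos <- element_positions(geo, g)
  # oracle: direct evaluation of the stated binning formula per element
  x <- g$origin[1] + 16 * g$spacing
  y <- g$origin[2] + 9 * g$spacing
  for (e in 1:4) {
    d <- sqrt((x - pos[e, 1])^2 + (y - pos[e, 2])^2)
    s <- d * 1e-3 / geo$sound_speed * geo$sampling_rate
    s0 <- floor(s); f <- s - s0
    amp <- 2.5 / max(d, g$spacing)
    expected <- rep(0, ncol(gram$values))
    expected[s0 + 1] <- amp * (1 - f)
    expected[s0 + 2] <- amp * f
    expect_equal(gram$values[e, ], expected, tolerance = 1e-12)
  }
})

test_that("defaults match the acquisition hardware: 128 channels at 40 MHz", {
  geo <- array_geometry()
  expect_equal(geo$n_elements, 128L)
  expect_equal(geo$sampling_rate, 4e7)
  g <- image_grid(16, 16, spacing = 0.5)
  gram <- simulate_channels(
    pressure_source_map(matrix(1, 16, 16), g), geo, 0)
  expect_equal(nrow(gram$values), 128)
})

test_that("the un-filtered operator is linear in the source", {
  g <- tiny_grid()
  geo <- tiny_geometry()
  set.seed(11)
  x <- matrix(runif(1024), 32, 32); y <- matrix(runif(1024), 32, 32)
  f <- function(m) simulate_channels(pressure_source_map(m, g), geo, 45)$values
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-10)
  expect_true(all(f(x * 0) == 0))
})

test_that("forward and adjoint agree with the dense-matrix oracle", {
  g <- image_grid(12, 12, spacing = 1.5)
  geo <- tiny_geometry(n_elements = 5, pitch = 4)
  ang <- 33
  A <- dense_forward_matrix(g, geo, ang)
  set.seed(21)
  for (i in 1:5) {
    x <- matrix(runif(144), 12, 12)
    gr <- simulate_channels(pressure_source_map(x, g), geo, ang)
    expect_equal(as.vector(gr$values), as.vector(A %*% as.vector(x)),
                 tolerance = 1e-12)
    y <- matrix(rnorm(length(gr$values)), nrow(gr$values), ncol(gr$values))
    adj <- adjoint_channels(channel_gram(y, ang, geo), g)
    expect_equal(as.vector(adj$values),
                 as.vector(t(A) %*% as.vector(y)), tolerance = 1e-12)
  }
})

test_that("simulating at angle theta equals simulating the pre-rotated source at 0", {
  g <- tiny_grid(33)
  geo <- tiny_geometry()
  src <- generate_phantom(centered_config(), g)
  a <- simulate_channels(src, geo, 72)$values
  pre <- pressure_source_map(pmax(rotate_image(src$values, -72, g), 0), g)
  b <- simulate_channels(pre, geo, 0)$values
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("12-bit quantization stays within the stated bound", {
  g <- tiny_grid()
  geo <- tiny_geometry()
  geo12 <- array_geometry(n_elements = 16, pitch = 3, standoff = 40,
                          quantization_bits = 12)
  src <- generate_phantom(centered_config(), g)
  raw <- simulate_channels(src, geo, 30)$values
  quant <- simulate_channels(src, geo12, 30)$values
  full_scale <- max(abs(raw))
  expect_gt(max(abs(raw - quant)), 0)      # quantization actually happened
  expect_lte(max(abs(raw - quant)), full_scale / 2^12)
})

test_that("too-short records raise an error naming the minimal length", {
  g <- tiny_grid()
  need <- required_samples(tiny_geometry(), g)
  geo <- array_geometry(n_elements = 16, pitch = 3, standoff = 40,
                        n_samples = need - 100L)
  expect_error(
    simulate_channels(pressure_source_map(matrix(1, 32, 32), g), geo, 0),
    sprintf("n_samples >= %d", need))
})
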
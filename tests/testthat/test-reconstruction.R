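test_that("back-projection is linear and zero-preserving", {
  g <- tiny_grid()
  geo <- tiny_geometry()
  n <- required_samples(geo, g)
  z <- backproject(channel_gram(matrix(0, 16, n), 10, geo), g)
  expect_true(all(z$values == 0))
  expect_equal(z$view_angle, 10)

  set.seed(3)
  g1 <- matrix(rnorm(16 * n), 16, n); g2 <- matrix(rnorm(16 * n), 16, n)
  b <- function(m) backproject(channel_gram(m, 0, geo), g)$values
  expect_equal(b(2 * g1 - g2), 2 * b(g1) - b(g2), tolerance = 1e-10)
})

test_that("back-projection equals the adjoint core up to 1/n_elements", {
  g <- tiny_grid()
  geo <- tiny_geometry()
  src <- generate_phantom(centered_config(), g)
  gram <- simulate_channels(src, geo, 0)  # at 0 deg the rotation is identity
  bp <- backproject(gram, g)
  adj <- adjoint_channels(gram, g)
  expect_equal(bp$values, adj$values / geo$n_elements, tolerance = 1e-12)
})

test_that("a single view at angle zero composites to itself", {
  g <- tiny_grid()
  geo <- tiny_geometry()
  gram <- simulate_channels(generate_phantom(centered_config(), g), geo, 0)
  s <- backproject(gram, g)
  full <- composite_full_view(list(s), g)
  expect_equal(full$values, s$values)
  expect_equal(full$n_views, 1L)
})

test_that("compositing is permutation-invariant and mean-preserving", {
  g <- tiny_grid(33)
  geo <- tiny_geometry()
  src <- generate_phantom(centered_config(), g)
  angles <- (0:7) * 45
  singles <- lapply(angles, function(a)
    backproject(simulate_channels(src, geo, a), g))
  f1 <- composite_full_view(singles, g)
  f2 <- composite_full_view(rev(singles), g)
  expect_equal(f1$values, f2$values)
  expect_equal(f1$n_views, 8L)

  # composite mass equals the mean of the de-rotated views' masses
  derot_sums <- vapply(singles, function(s)
    sum(rotate_image(s$values, s$view_angle, g)), numeric(1))
  # exact up to interpolation of mass near borders; the identity itself
  # holds to machine precision because the mean is taken after de-rotation
  expect_equal(sum(f1$values), mean(derot_sums), tolerance = 1e-12)
  expect_lt(abs(sum(f1$values) - mean(derot_sums)) /
              max(abs(sum(f1$values)), 1e-12), 0.01)
})

test_that("full-view compositing collapses a point source to its location", {
  g <- tiny_grid()
  geo <- tiny_geometry()
  set.seed(5)
  for (trial in 1:3) {
    m <- matrix(0, 32, 32)
    rc <- sample(8:24, 2, replace = TRUE)
    m[rc[1], rc[2]] <- 1
    src <- pressure_source_map(m, g)
    singles <- lapply((0:35) * 10, function(a)
      backproject(simulate_channels(src, geo, a), g))
    full <- composite_full_view(singles, g)
    am <- which(full$values == max(full$values), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(am - rc)), 1)
  }
})

test_that("build_viewset orchestrates n views deterministically", {
  g <- tiny_grid()
  geo <- tiny_geometry()
  cfg <- centered_config()
  vs <- build_viewset(cfg, geo, g, n_views = 12, dataset_id = "d0")
  expect_length(vs$grams, 12)
  expect_length(vs$singles, 12)
  expect_equal(vs$angles, (0:11) * 30)
  expect_s3_class(vs$full, "full_view_image")

  vs2 <- build_viewset(cfg, geo, g, n_views = 12, dataset_id = "d0")
  expect_identical(vs$full$values, vs2$full$values)
  expect_identical(vs$grams[[5]]$values, vs2$grams[[5]]$values)

  vs1 <- build_viewset(cfg, geo, g, n_views = 1)
  expect_equal(vs1$full$values, vs1$singles[[1]]$values)
})

test_that("a rotationally symmetric phantom yields view-invariant data", {
  # rotating a symmetric source is a no-op up to interpolation, so every
  # view must measure (and reconstruct) the same thing within a small
  # fraction of the peak
  g <- tiny_grid(33)
  geo <- tiny_geometry()
  src <- ring_phantom(g)
  angles <- c(0, 22.5, 45, 100, 237.5)
  grams <- lapply(angles, function(a) simulate_channels(src, geo, a))
  singles <- lapply(grams, backproject, grid = g)
  gp <- max(abs(grams[[1]]$values))
  sp <- max(abs(singles[[1]]$values))
  for (k in 2:5) {
    expect_lt(max(abs(grams[[k]]$values - grams[[1]]$values)), 0.02 * gp)
    expect_lt(max(abs(singles[[k]]$values - singles[[1]]$values)),
              0.02 * sp)
  }

  # consequently the composite equals the rotation-average of any one view
  nv <- 16
  all_singles <- lapply((0:(nv - 1)) * 360 / nv, function(a)
    backproject(simulate_channels(src, geo, a), g))
  full <- composite_full_view(all_singles, g)
  for (j in c(1, 6)) {
    rot_avg <- Reduce(`+`, lapply((0:(nv - 1)) * 360 / nv, function(a)
      rotate_image(all_singles[[j]]$values, a, g))) / nv
    expect_lt(max(abs(rot_avg - full$values)), 0.02 * max(abs(full$values)))
  }
})

test_that("compositing validates its inputs", {
  g <- tiny_grid()
  expect_error(composite_full_view(list(), g), "non-empty")
  s1 <- single_view_image(matrix(0, 32, 32), 0, g)
  s2 <- single_view_image(matrix(0, 32, 32), 0, g)
  expect_error(composite_full_view(list(s1, s2), g), "distinct")
  g2 <- tiny_grid(16)
  s3 <- single_view_image(matrix(0, 16, 16), 90, g2)
  expect_error(composite_full_view(list(s1, s3), g), "same grid")
})
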
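test_that("normalize01 is an idempotent min-max map", {
  set.seed(1)
  x <- matrix(runif(64), 8, 8)
  x[1] <- 0; x[64] <- 1
  expect_equal(normalize01(x), x)
  ramp <- matrix(seq(5, 6, length.out = 64), 8, 8)
  expect_equal(normalize01(ramp), (ramp - 5) / 1)
  n1 <- normalize01(matrix(rnorm(64), 8, 8))
  expect_equal(normalize01(n1), n1)
  expect_error(normalize01(matrix(2, 4, 4)), "constant")
  expect_warning(z <- normalize01(matrix(2, 4, 4), on_constant = "zero"),
                 "constant")
  expect_true(all(z == 0))
})

test_that("rmse and psnr match closed forms and brute-force oracles", {
  a0 <- matrix(0, 16, 16); a1 <- matrix(0.1, 16, 16)
  expect_equal(eat_rmse(a0, a0), 0)
  expect_equal(eat_rmse(a0, a1), 0.1)
  expect_equal(as.numeric(eat_psnr(a0, a1)), 20)
  a01 <- matrix(0.01, 16, 16)
  expect_equal(as.numeric(eat_psnr(a0, a01)), 40)
  p <- eat_psnr(a0, a0)
  expect_equal(as.numeric(p), 99)
  expect_true(attr(p, "capped"))

  set.seed(2)
  for (i in 1:5) {
    a <- rand_image(64); b <- rand_image(64)
    # elementwise-loop oracle
    acc <- 0
    for (r in 1:64) for (c in 1:64) acc <- acc + (a[r, c] - b[r, c])^2
    expect_equal(eat_rmse(a, b), sqrt(acc / 4096), tolerance = 1e-12)
    expect_equal(as.numeric(eat_psnr(a, b)),
                 20 * log10(1 / sqrt(acc / 4096)), tolerance = 1e-9)
  }
})

test_that("rmse behaves as a metric and psnr decreases with it", {
  set.seed(4)
  a <- rand_image(32); b <- rand_image(32)
  expect_equal(eat_rmse(a, b), eat_rmse(b, a))
  expect_gte(eat_rmse(a, b), 0)
  expect_equal(eat_rmse(a, a), 0)
  r <- seq(0.01, 0.5, by = 0.05)
  psnrs <- 20 * log10(1 / r)
  expect_true(all(diff(psnrs) < 0))
})

test_that("ssim matches the scikit-image reference implementation", {
  set.seed(6)
  for (i in 1:3) {
    a <- rand_image(64); b <- rand_image(64)
    expect_equal(eat_ssim(a, b), skimage_ssim(a, b), tolerance = 1e-6)
  }
  a <- rand_image(32)
  expect_equal(eat_ssim(a, a), 1)
  b <- rand_image(32)
  expect_equal(eat_ssim(a, b), eat_ssim(b, a), tolerance = 1e-12)
  expect_error(eat_ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "at least")
})

test_that("ssim matches a direct windowed-statistics oracle", {
  # independent R oracle: loop over fully-interior 11x11 windows
  set.seed(8)
  a <- rand_image(24); b <- rand_image(24)
  k <- exp(-0.5 * ((-5:5) / 1.5)^2); k <- k / sum(k)
  W <- outer(k, k)
  C1 <- 0.01^2; C2 <- 0.03^2
  vals <- c()
  for (r in 6:19) for (c in 6:19) {
    wa <- a[(r - 5):(r + 5), (c - 5):(c + 5)]
    wb <- b[(r - 5):(r + 5), (c - 5):(c + 5)]
    ux <- sum(W * wa); uy <- sum(W * wb)
    vx <- sum(W * wa^2) - ux^2; vy <- sum(W * wb^2) - uy^2
    vxy <- sum(W * wa * wb) - ux * uy
    vals <- c(vals, ((2 * ux * uy + C1) * (2 * vxy + C2)) /
                ((ux^2 + uy^2 + C1) * (vx + vy + C2)))
  }
  expect_equal(eat_ssim(a, b), mean(vals), tolerance = 1e-12)
})

test_that("dice_iso matches set-count oracles and edge conventions", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  a[1, 1:4] <- 1; b[1, 3:4] <- 1; b[2, 1:2] <- 1
  # |A| = 4, |B| = 4, |A and B| = 2 -> 0.5
  expect_equal(dice_iso(a, b, 0.5), 0.5)
  expect_equal(dice_iso(a, a, 0.3), 1)
  disj <- matrix(0, 4, 4); disj[4, ] <- 1
  expect_equal(dice_iso(a, disj, 0.5), 0)
  expect_equal(dice_iso(matrix(0, 4, 4), matrix(0, 4, 4), 0.5), 1)
  expect_equal(dice_iso(a, matrix(0, 4, 4), 0.5), 0)
  expect_error(dice_iso(a, b, 1.5), "level")

  set.seed(10)
  for (i in 1:5) {
    x <- rand_image(64); y <- rand_image(64)
    na <- nb <- ni <- 0
    for (r in 1:64) for (c in 1:64) {
      inA <- x[r, c] >= 0.3; inB <- y[r, c] >= 0.3
      na <- na + inA; nb <- nb + inB; ni <- ni + (inA && inB)
    }
    expect_identical(dice_iso(x, y, 0.3), 2 * ni / (na + nb))
    expect_equal(dice_iso(x, y, 0.3), dice_iso(y, x, 0.3))
  }
})

test_that("evaluate_pairs aggregates mean and population sd exactly", {
  set.seed(12)
  refs <- list(rand_image(16), rand_image(16))
  cands <- list(refs[[1]], rand_image(16))
  rep <- evaluate_pairs(cands, refs, arm = "test")
  expect_equal(nrow(rep$per_sample), 2)
  expect_equal(rep$per_sample$rmse[1], 0)
  expect_equal(rep$per_sample$ssim[1], 1)
  expect_true(all(rep$per_sample$dice_10 <= 1))

  r <- rep$per_sample$rmse
  agg <- rep$aggregate
  expect_equal(agg$mean[agg$metric == "rmse"], mean(r))
  expect_equal(agg$sd[agg$metric == "rmse"],
               sqrt(mean((r - mean(r))^2)))

  # identical pairs: all-zero errors, unit similarity
  same <- evaluate_pairs(refs, refs, arm = "same")
  expect_true(all(same$per_sample$rmse == 0))
  expect_true(all(same$per_sample$ssim == 1))
  expect_true(all(same$per_sample$dice_20 == 1))
})

test_that("metric reports round-trip to CSV with both arms", {
  set.seed(14)
  refs <- list(rand_image(16), rand_image(16))
  r1 <- evaluate_pairs(list(rand_image(16), rand_image(16)), refs,
                       arm = "single_view")
  r2 <- evaluate_pairs(refs, refs, arm = "enhanced")
  merged <- merge_reports(r1, r2)
  expect_setequal(unique(merged$per_sample$arm),
                  c("single_view", "enhanced"))
  td <- withr::local_tempdir()
  paths <- write_metrics_csv(merged, file.path(td, "m"))
  per <- read.csv(paths["per_sample"])
  expect_equal(nrow(per), 4)
  agg <- read.csv(paths["aggregate"])
  expect_true(all(c("arm", "metric", "mean", "sd") %in% names(agg)))
})
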
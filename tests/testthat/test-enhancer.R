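small_cfg <- function() unet_config(input_size = c(32, 32), depth = 2,
                                    base_filters = 4)

test_that("network configuration enforces divisibility and bounds", {
  expect_error(unet_config(input_size = c(100, 100), depth = 3),
               "divisible")
  expect_error(unet_config(dropout_rate = 1), "dropout_rate")
  cfg <- unet_config(input_size = c(64, 64), depth = 2)
  expect_equal(cfg$input_size, c(64L, 64L))
  # defaults mirror the training recipe
  tc <- train_config()
  expect_equal(tc$learning_rate, 7e-4)
  expect_equal(tc$batch_size, 1L)
  expect_equal(tc$optimizer, "adam")
  expect_equal(tc$loss, "dssim")
})

test_that("weight initialization is seeded and the output shape matches", {
  cfg <- small_cfg()
  w1 <- eatomo:::with_seed(42, eatomo:::unet_init_weights(cfg))
  w2 <- eatomo:::with_seed(42, eatomo:::unet_init_weights(cfg))
  expect_identical(w1, w2)
  x <- rand_image(32, seed = 1)
  out <- eatomo:::unet_forward(w1, cfg, x, training = FALSE)$out
  expect_equal(dim(out), c(32, 32))
  expect_true(all(is.finite(out)))
})

test_that("dssim loss equals one minus the metric ssim", {
  set.seed(20)
  a <- rand_image(32); b <- rand_image(32)
  expect_equal(dssim_loss(a, a), 0)
  expect_equal(dssim_loss(a, b), 1 - eat_ssim(a, b), tolerance = 1e-12)
  expect_gte(dssim_loss(a, b), 0)
  expect_lte(dssim_loss(a, b), 2)
  expect_equal(dssim_loss(list(a, b), list(a, b)), 0)
})

test_that("the dssim gradient matches central finite differences", {
  set.seed(22)
  a <- rand_image(16); b <- rand_image(16)
  gr <- dssim_grad(a, b)
  expect_equal(gr$loss, dssim_loss(a, b))
  h <- 1e-6
  idx <- rbind(c(8, 8), c(1, 1), c(16, 3), c(4, 12))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ap <- a; ap[i, j] <- ap[i, j] + h
    am <- a; am[i, j] <- am[i, j] - h
    num <- (dssim_loss(ap, b) - dssim_loss(am, b)) / (2 * h)
    expect_equal(gr$grad[i, j], num, tolerance = 1e-4)
  }
})

test_that("backprop gradients match finite differences through the whole net", {
  cfg <- unet_config(input_size = c(16, 16), depth = 2, base_filters = 2,
                     dropout_rate = 0)
  w <- eatomo:::with_seed(1, eatomo:::unet_init_weights(cfg))
  x <- rand_image(16, seed = 2); y <- rand_image(16, seed = 3)
  fwd <- eatomo:::unet_forward(w, cfg, x, training = FALSE)
  dg <- dssim_grad(fwd$out, y)
  g <- eatomo:::unet_backward(w, cfg, fwd, dg$grad)
  lossfun <- function(w) dssim_loss(
    eatomo:::unet_forward(w, cfg, x, training = FALSE)$out, y)
  h <- 1e-5
  probes <- list(
    list(get = function(w) w$enc[[1]]$conv1$W[1, 1],
         set = function(w, v) { w$enc[[1]]$conv1$W[1, 1] <- v; w },
         g = g$enc[[1]]$conv1$W[1, 1]),
    list(get = function(w) w$enc[[2]]$bn1$gamma[1],
         set = function(w, v) { w$enc[[2]]$bn1$gamma[1] <- v; w },
         g = g$enc[[2]]$bn1$gamma[1]),
    list(get = function(w) w$dec[[1]]$conv2$W[2, 7],
         set = function(w, v) { w$dec[[1]]$conv2$W[2, 7] <- v; w },
         g = g$dec[[1]]$conv2$W[2, 7]),
    list(get = function(w) w$bottom$bn2$beta[3],
         set = function(w, v) { w$bottom$bn2$beta[3] <- v; w },
         g = g$bottom$bn2$beta[3]),
    list(get = function(w) w$final$W[1, 2],
         set = function(w, v) { w$final$W[1, 2] <- v; w },
         g = g$final$W[1, 2]))
  for (p in probes) {
    num <- (lossfun(p$set(w, p$get(w) + h)) -
              lossfun(p$set(w, p$get(w) - h))) / (2 * h)
    expect_equal(p$g, num, tolerance = 1e-4)
  }
})

test_that("training the identity task reduces the loss, reproducibly", {
  cfg <- unet_config(input_size = c(32, 32), depth = 2, base_filters = 4,
                     dropout_rate = 0.5)
  set.seed(30)
  imgs <- lapply(1:4, function(i) {
    m <- matrix(0, 32, 32)
    m[sample(6:26, 1) + (-2:2), sample(6:26, 1) + (-2:2)] <- 1
    eatomo:::gauss_blur(m, 1.5)
  })
  pairs <- lapply(imgs, function(m) list(x = normalize01(m),
                                         y = normalize01(m)))
  tc <- train_config(max_epochs = 12, seed = 5)
  fit <- train_enhancer(pairs, pairs, cfg, tc)
  log <- fit$training_log
  expect_equal(nrow(log), 12)
  expect_lt(log$train_loss[12], log$train_loss[1])
  expect_lt(min(log$val_loss), log$val_loss[1])
  expect_equal(fit$best_epoch, which.min(log$val_loss))

  fit2 <- train_enhancer(pairs, pairs, cfg, tc)
  expect_identical(fit$training_log, fit2$training_log)
  expect_identical(fit$weights, fit2$weights)
})

test_that("inference is deterministic, shape-preserving and clampable", {
  cfg <- small_cfg()
  pairs <- list(list(x = rand_image(32, seed = 1),
                     y = rand_image(32, seed = 2)))
  fit <- train_enhancer(pairs, pairs, cfg, train_config(max_epochs = 1,
                                                        seed = 3))
  x <- rand_image(32, seed = 9)
  o1 <- predict(fit, x); o2 <- predict(fit, x)
  expect_identical(o1, o2)
  expect_equal(dim(o1), c(32, 32))
  oc <- predict(fit, x, clamp01 = TRUE)
  expect_true(all(oc >= 0 & oc <= 1))
  expect_identical(enhance(fit, x), o1)
  expect_error(predict(fit, rand_image(16)), "input_size")
  # list input maps over elements
  both <- predict(fit, list(x, x))
  expect_identical(both[[1]], both[[2]])
})

test_that("dataset splits are disjoint, exhaustive in count, and seeded", {
  sets <- lapply(1:12, function(i) list(dataset_id = sprintf("d%02d", i)))
  sp <- split_datasets(sets, 8, 2, 2, seed = 4)
  ids <- function(l) vapply(l, `[[`, "", "dataset_id")
  all_ids <- c(ids(sp$train), ids(sp$val), ids(sp$test))
  expect_length(all_ids, 12)
  expect_false(anyDuplicated(all_ids) > 0)
  sp2 <- split_datasets(sets, 8, 2, 2, seed = 4)
  expect_identical(ids(sp$train), ids(sp2$train))
  sp0 <- split_datasets(sets, 8, 2, 0, seed = 4)
  expect_length(sp0$test, 0)
  expect_error(split_datasets(sets, 10, 2, 2), "exceed")
})
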
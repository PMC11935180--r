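# Modified U-Net: encoder-decoder with skip connections, two
# conv(3x3)+batch-norm+ReLU blocks per scale, max-pool down / nearest
# upsample + concatenate up, dropout at the U-bottom, linear 1x1 output.
# Implemented directly on GEMM conv kernels (src/unet_ops.cpp) with analytic
# backprop; no external deep-learning framework is involved.

#' Enhancer network configuration
#'
#' @param input_size `c(rows, cols)` of the input images; must be divisible
#'   by `2^depth`. Default 256 x 256.
#' @param depth number of down/up-sampling levels (default 4).
#' @param base_filters feature channels at the top level, doubling per
#'   level (default 32).
#' @param dropout_rate dropout fraction applied at the U-bottom only
#'   (default 0.5).
#' @param batch_norm use batch normalization after each convolution
#'   (default `TRUE`). With batch size 1 the batch statistics are the
#'   per-sample spatial statistics; the same statistics are used at
#'   inference, keeping prediction deterministic.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(input_size = c(256L, 256L), depth = 4L,
                        base_filters = 32L, dropout_rate = 0.5,
                        batch_norm = TRUE) {
  input_size <- as.integer(input_size)
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  if (length(input_size) != 2L || any(input_size < 2^depth))
    stop("`input_size` must be two dims, each >= 2^depth", call. = FALSE)
  if (any(input_size %% 2^depth != 0L))
    stop("`input_size` must be divisible by 2^depth", call. = FALSE)
  if (depth < 1L) stop("`depth` must be >= 1", call. = FALSE)
  if (base_filters < 1L) stop("`base_filters` must be >= 1", call. = FALSE)
  stopifnot_scalar_num(dropout_rate, "dropout_rate")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  structure(list(input_size = input_size, depth = depth,
                 base_filters = base_filters, dropout_rate = dropout_rate,
                 batch_norm = isTRUE(batch_norm)),
            class = "unet_config")
}

#' Training configuration for the enhancer
#'
#' Defaults follow the training recipe: Adam with learning rate 0.0007,
#' batch size 1, structural-dissimilarity (DSSIM) loss, best checkpoint
#' selected by validation loss.
#'
#' @param learning_rate Adam step size (default 7e-4).
#' @param batch_size samples per gradient step (default 1).
#' @param max_epochs number of passes over the training pairs.
#' @param seed integer seed for weight initialization, shuffling and
#'   dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 7e-4, batch_size = 1L,
                         max_epochs = 30L, seed = 1L) {
  stopifnot_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  batch_size <- as.integer(batch_size)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  max_epochs <- as.integer(max_epochs)
  if (max_epochs < 1L) stop("`max_epochs` must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 optimizer = "adam", loss = "dssim",
                 max_epochs = max_epochs, seed = as.integer(seed)),
            class = "train_config")
}

# channel widths per encoder level l = 1..depth (bottom is depth + 1)
unet_channels <- function(config) config$base_filters * 2^(0:config$depth)

conv_init <- function(c_in, c_out, k) {
  # He initialization for ReLU nets
  sd <- sqrt(2 / (c_in * k * k))
  list(W = matrix(rnorm(c_out * c_in * k * k, sd = sd), c_out, c_in * k * k),
       b = rep(0, c_out), k = k)
}

bn_init <- function(c_out) list(gamma = rep(1, c_out), beta = rep(0, c_out))

block_init <- function(c_in, c_out, bn) {
  list(conv1 = conv_init(c_in, c_out, 3L),
       bn1 = if (bn) bn_init(c_out),
       conv2 = conv_init(c_out, c_out, 3L),
       bn2 = if (bn) bn_init(c_out))
}

# Initialize all weights; consumes the current RNG stream.
unet_init_weights <- function(config) {
  ch <- unet_channels(config)
  D <- config$depth
  enc <- lapply(seq_len(D), function(l)
    block_init(if (l == 1L) 1L else ch[l - 1], ch[l], config$batch_norm))
  bottom <- block_init(ch[D], ch[D + 1], config$batch_norm)
  dec <- lapply(seq_len(D), function(l)
    block_init(ch[l + 1] + ch[l], ch[l], config$batch_norm))
  final <- conv_init(ch[1], 1L, 1L)
  list(enc = enc, bottom = bottom, dec = dec, final = final)
}

BN_EPS <- 1e-5

bn_forward <- function(x, par) {
  # per-channel normalization over the spatial field of one sample
  C <- dim(x)[3]
  out <- x
  mu <- var <- istd <- numeric(C)
  xhat <- x
  for (c in seq_len(C)) {
    sl <- x[, , c]
    mu[c] <- mean(sl)
    var[c] <- mean((sl - mu[c])^2)
    istd[c] <- 1 / sqrt(var[c] + BN_EPS)
    xh <- (sl - mu[c]) * istd[c]
    xhat[, , c] <- xh
    out[, , c] <- par$gamma[c] * xh + par$beta[c]
  }
  list(out = out, xhat = xhat, mu = mu, istd = istd)
}

bn_backward <- function(dout, cache, par) {
  C <- dim(dout)[3]
  dx <- dout
  dgamma <- dbeta <- numeric(C)
  N <- dim(dout)[1] * dim(dout)[2]
  for (c in seq_len(C)) {
    d <- dout[, , c]; xh <- cache$xhat[, , c]
    dgamma[c] <- sum(d * xh)
    dbeta[c] <- sum(d)
    dxh <- d * par$gamma[c]
    # standard batch-norm backward over N spatial positions
    dx[, , c] <- cache$istd[c] / N *
      (N * dxh - sum(dxh) - xh * sum(dxh * xh))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

block_forward <- function(x, par, bn) {
  y1 <- cpp_conv2d(x, par$conv1$W, par$conv1$b, par$conv1$k)
  if (bn) { b1 <- bn_forward(y1, par$bn1); z1 <- b1$out } else { b1 <- NULL; z1 <- y1 }
  r1 <- pmax(z1, 0)
  y2 <- cpp_conv2d(r1, par$conv2$W, par$conv2$b, par$conv2$k)
  if (bn) { b2 <- bn_forward(y2, par$bn2); z2 <- b2$out } else { b2 <- NULL; z2 <- y2 }
  r2 <- pmax(z2, 0)
  list(out = r2,
       cache = list(x = x, z1 = z1, r1 = r1, z2 = z2, b1 = b1, b2 = b2))
}

block_backward <- function(dout, cache, par, bn) {
  g <- list()
  d <- dout * (cache$z2 > 0)
  if (bn) {
    bb <- bn_backward(d, cache$b2, par$bn2)
    g$bn2 <- list(gamma = bb$dgamma, beta = bb$dbeta)
    d <- bb$dx
  }
  cb <- cpp_conv2d_bwd(cache$r1, par$conv2$W, d, par$conv2$k)
  g$conv2 <- list(W = cb$dW, b = as.numeric(cb$db))
  d <- cb$dx * (cache$z1 > 0)
  if (bn) {
    bb <- bn_backward(d, cache$b1, par$bn1)
    g$bn1 <- list(gamma = bb$dgamma, beta = bb$dbeta)
    d <- bb$dx
  }
  cb <- cpp_conv2d_bwd(cache$x, par$conv1$W, d, par$conv1$k)
  g$conv1 <- list(W = cb$dW, b = as.numeric(cb$db))
  list(dx = cb$dx, grads = g)
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# Forward pass. `x` is an H x W matrix in [0, 1]. When `training`, the
# bottleneck dropout mask is drawn from the current RNG stream (inverted
# dropout); at inference dropout is off and the pass is deterministic.
unet_forward <- function(weights, config, x, training = FALSE) {
  bn <- config$batch_norm
  D <- config$depth
  h <- array(x, c(nrow(x), ncol(x), 1))
  skips <- caches <- vector("list", D)
  pools <- vector("list", D)
  for (l in seq_len(D)) {
    bf <- block_forward(h, weights$enc[[l]], bn)
    skips[[l]] <- bf$out; caches[[l]] <- bf$cache
    mp <- cpp_maxpool2(bf$out)
    pools[[l]] <- mp$idx
    h <- mp$out
  }
  bot <- block_forward(h, weights$bottom, bn)
  h <- bot$out
  drop_mask <- NULL
  if (training && config$dropout_rate > 0) {
    keep <- 1 - config$dropout_rate
    drop_mask <- array(
      (runif(length(h)) < keep) / keep, dim(h))
    h <- h * drop_mask
  }
  dec_caches <- vector("list", D)
  for (l in rev(seq_len(D))) {
    up <- cpp_upsample2(h)
    cat_in <- concat_c(up, skips[[l]])
    bf <- block_forward(cat_in, weights$dec[[l]], bn)
    dec_caches[[l]] <- list(cache = bf$cache, n_up = dim(up)[3])
    h <- bf$out
  }
  out <- cpp_conv2d(h, weights$final$W, weights$final$b, weights$final$k)
  list(out = out[, , 1],
       cache = list(enc = caches, pools = pools, bottom = bot$cache,
                    drop_mask = drop_mask, dec = dec_caches,
                    final_in = h))
}

# Backward pass; `dout` is dLoss/dOutput (H x W matrix).
unet_backward <- function(weights, config, fwd, dout) {
  bn <- config$batch_norm
  D <- config$depth
  g <- list(enc = vector("list", D), dec = vector("list", D))
  d <- array(dout, c(nrow(dout), ncol(dout), 1))
  cb <- cpp_conv2d_bwd(fwd$cache$final_in, weights$final$W, d,
                       weights$final$k)
  g$final <- list(W = cb$dW, b = as.numeric(cb$db))
  d <- cb$dx
  dskips <- vector("list", D)
  for (l in seq_len(D)) {
    bb <- block_backward(d, fwd$cache$dec[[l]]$cache, weights$dec[[l]], bn)
    g$dec[[l]] <- bb$grads
    n_up <- fwd$cache$dec[[l]]$n_up
    total <- dim(bb$dx)[3]
    dup <- bb$dx[, , seq_len(n_up), drop = FALSE]
    dskips[[l]] <- bb$dx[, , (n_up + 1):total, drop = FALSE]
    d <- cpp_upsample2_bwd(dup)
  }
  if (!is.null(fwd$cache$drop_mask)) d <- d * fwd$cache$drop_mask
  bb <- block_backward(d, fwd$cache$bottom, weights$bottom, bn)
  g$bottom <- bb$grads
  d <- bb$dx
  for (l in rev(seq_len(D))) {
    dpool <- cpp_maxpool2_bwd(d, fwd$cache$pools[[l]])
    dtotal <- dpool + dskips[[l]]
    bb <- block_backward(dtotal, fwd$cache$enc[[l]], weights$enc[[l]], bn)
    g$enc[[l]] <- bb$grads
    d <- bb$dx
  }
  g
}

#' Structural-dissimilarity (DSSIM) training loss
#'
#' `1 - SSIM(pred, target)` with the same constants and window as
#' [eat_ssim()], averaged over a batch. The gradient with respect to the
#' prediction is analytic (the Gaussian-window filter is self-adjoint under
#' the zero-padding convention, and only cropped-region SSIM values enter
#' the mean).
#'
#' @param pred,target numeric matrices (or lists of matrices) in \[0, 1\].
#' @return For `dssim_loss`, a scalar in \[0, 2\]. `dssim_grad` returns
#'   `list(loss, grad)` for a single pair.
#' @export
dssim_loss <- function(pred, target) {
  if (is.matrix(pred)) { pred <- list(pred); target <- list(target) }
  if (length(pred) != length(target))
    stop("`pred` and `target` must have equal length", call. = FALSE)
  mean(vapply(seq_along(pred), function(i) {
    check_pair(pred[[i]], target[[i]])
    1 - eat_ssim(pred[[i]], target[[i]])
  }, numeric(1)))
}

#' @rdname dssim_loss
#' @export
dssim_grad <- function(pred, target) {
  check_pair(pred, target)
  fl <- ssim_fields(pred, target)
  Nc <- sum(fl$crop)
  B1B2 <- fl$B1 * fl$B2
  T1 <- 2 * (fl$uy * fl$A2 * fl$B1 - fl$ux * fl$A1 * fl$A2) /
    (fl$B1^2 * fl$B2)
  T2 <- -fl$A1 * fl$A2 / (fl$B1 * fl$B2^2)
  T3 <- 2 * fl$A1 / B1B2
  T1[!fl$crop] <- 0; T2[!fl$crop] <- 0; T3[!fl$crop] <- 0
  f <- function(x) cpp_sepconv_same(x, fl$k)
  dmssim <- (f(T1) + 2 * pred * f(T2) - 2 * f(T2 * fl$ux) +
               target * f(T3) - f(T3 * fl$uy)) / Nc
  list(loss = 1 - fl$mssim, grad = -dmssim)
}

# --- Adam over the nested weight list ---------------------------------------

adam_state_init <- function(weights) {
  walk <- function(w) {
    if (is.list(w)) lapply(w, walk)
    else if (is.numeric(w)) list(m = w * 0, v = w * 0)
    else w
  }
  list(t = 0L, par = walk(weights))
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(w, g, s) {
    if (is.numeric(w) && !is.list(w)) {
      if (is.null(g)) return(list(w = w, s = s))
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      list(w = w - lr * mhat / (sqrt(vhat) + eps), s = s)
    } else if (is.list(w)) {
      for (nm in names(w)) {
        if (is.null(w[[nm]])) next
        if (nm == "k") next  # kernel-size constant, not a parameter
        res <- walk(w[[nm]], g[[nm]], s[[nm]])
        w[[nm]] <- res$w; s[[nm]] <- res$s
      }
      list(w = w, s = s)
    } else list(w = w, s = s)
  }
  # enc/dec are unnamed lists of blocks: recurse positionally
  walk_pos <- function(w, g, s) {
    if (is.list(w) && is.null(names(w))) {
      for (i in seq_along(w)) {
        res <- walk_pos(w[[i]], g[[i]], s[[i]])
        w[[i]] <- res$w; s[[i]] <- res$s
      }
      return(list(w = w, s = s))
    }
    if (is.list(w)) {
      for (nm in names(w)) {
        if (is.null(w[[nm]]) || nm == "k") next
        res <- walk_pos(w[[nm]], g[[nm]], s[[nm]])
        w[[nm]] <- res$w; s[[nm]] <- res$s
      }
      return(list(w = w, s = s))
    }
    walk(w, g, s)
  }
  res <- walk_pos(weights, grads, state$par)
  list(weights = res$w, state = list(t = t, par = res$s))
}

# sum two grad trees of identical structure (for batch accumulation)
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.numeric(a) && !is.list(a)) return(a + b)
  for (i in seq_along(a)) if (!is.null(a[[i]])) a[[i]] <- grads_add(a[[i]], b[[i]])
  a
}

grads_scale <- function(a, s) {
  if (is.null(a)) return(a)
  if (is.numeric(a) && !is.list(a)) return(a * s)
  for (i in seq_along(a)) a[[i]] <- grads_scale(a[[i]], s)
  a
}
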
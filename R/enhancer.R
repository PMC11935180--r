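#' Fit the image-enhancing network on paired single/full-view images
#'
#' Trains the modified U-Net to map limited-angle single-view
#' reconstructions to full-view-quality images by minimizing the
#' structural-dissimilarity (DSSIM) loss with Adam. Inputs and targets are
#' expected min-max normalized to \[0, 1\]; validation pairs must come from
#' datasets disjoint from the training pairs (the split is by electrode
#' configuration, never by view). After each epoch the train and validation
#' losses are recorded; the returned weights are those of the epoch with
#' minimal validation loss.
#'
#' @param train_pairs,val_pairs non-empty lists of `list(x = , y = )` pairs
#'   of matrices matching `config$input_size` (x: single-view, y:
#'   full-view).
#' @param config a [unet_config()].
#' @param tc a [train_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `eat_enhancer` with elements `weights` (best
#'   checkpoint), `config`, `train_config`, `training_log` (data.frame
#'   epoch/train_loss/val_loss) and `best_epoch`.
#' @export
train_enhancer <- function(train_pairs, val_pairs, config = unet_config(),
                           tc = train_config(), verbose = FALSE) {
  check_pairs_arg <- function(pairs, name) {
    if (length(pairs) == 0L)
      stop(sprintf("`%s` must be non-empty", name), call. = FALSE)
    for (p in pairs) {
      if (!is.list(p) || is.null(p$x) || is.null(p$y))
        stop(sprintf("`%s` elements must be list(x = , y = )", name),
             call. = FALSE)
      if (!all(dim(p$x) == config$input_size) ||
          !all(dim(p$y) == config$input_size))
        stop(sprintf("`%s` images must match config$input_size", name),
             call. = FALSE)
    }
  }
  check_pairs_arg(train_pairs, "train_pairs")
  check_pairs_arg(val_pairs, "val_pairs")

  with_seed(tc$seed, {
    weights <- unet_init_weights(config)
    state <- adam_state_init(weights)
    n <- length(train_pairs)
    log_rows <- vector("list", tc$max_epochs)
    best <- list(val = Inf, weights = weights, epoch = 0L)
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample.int(n)
      train_losses <- numeric(n)
      i <- 1L
      while (i <= n) {
        take <- ord[i:min(i + tc$batch_size - 1L, n)]
        acc <- NULL
        for (j in take) {
          p <- train_pairs[[j]]
          fwd <- unet_forward(weights, config, p$x, training = TRUE)
          dg <- dssim_grad(fwd$out, p$y)
          if (!is.finite(dg$loss))
            stop(sprintf("non-finite training loss at epoch %d", epoch),
                 call. = FALSE)
          train_losses[which(ord == j)] <- dg$loss
          g <- unet_backward(weights, config, fwd, dg$grad)
          acc <- if (is.null(acc)) g else grads_add(acc, g)
        }
        if (length(take) > 1L) acc <- grads_scale(acc, 1 / length(take))
        st <- adam_step(weights, acc, state, tc$learning_rate)
        weights <- st$weights; state <- st$state
        i <- i + tc$batch_size
      }
      val_loss <- mean(vapply(val_pairs, function(p) {
        fwd <- unet_forward(weights, config, p$x, training = FALSE)
        1 - eat_ssim(fwd$out, p$y)
      }, numeric(1)))
      log_rows[[epoch]] <- data.frame(epoch = epoch,
                                      train_loss = mean(train_losses),
                                      val_loss = val_loss)
      if (val_loss < best$val)
        best <- list(val = val_loss, weights = weights, epoch = epoch)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        mean(train_losses), val_loss))
    }
    structure(list(weights = best$weights, config = config,
                   train_config = tc,
                   training_log = do.call(rbind, log_rows),
                   best_epoch = best$epoch),
              class = "eat_enhancer")
  })
}

#' @export
print.eat_enhancer <- function(x, ...) {
  cat(sprintf(
    "<eat_enhancer> U-Net depth %d, base %d filters, input %d x %d\n",
    x$config$depth, x$config$base_filters,
    x$config$input_size[1], x$config$input_size[2]))
  n <- nrow(x$training_log)
  cat(sprintf("  trained %d epochs (Adam, lr %g, batch %d, DSSIM loss)\n",
              n, x$train_config$learning_rate, x$train_config$batch_size))
  cat(sprintf("  best checkpoint: epoch %d, validation loss %.4f\n",
              x$best_epoch, x$training_log$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.eat_enhancer <- function(object, ...) {
  print(object)
  cat("\nTraining log (last rows):\n")
  print(utils::tail(object$training_log, 5), row.names = FALSE)
  n_par <- 0
  count <- function(w) {
    if (is.numeric(w) && !is.list(w)) n_par <<- n_par + length(w)
    else if (is.list(w)) for (nm in seq_along(w))
      if (!is.null(w[[nm]])) count(w[[nm]])
  }
  count(object$weights)
  cat(sprintf("\nParameters: %d\n", n_par))
  invisible(object)
}

#' Enhance a single-view image with a trained model
#'
#' Deterministic inference (dropout off). `predict()` is the generic
#' interface; `enhance()` is the domain-named equivalent.
#'
#' @param object a fitted `eat_enhancer`.
#' @param newdata a matrix in \[0, 1\] matching the model's input size, a
#'   list of such matrices, or a `single_view_image`.
#' @param clamp01 clamp the output into \[0, 1\] (the evaluation-time
#'   convention; the network's final activation is linear).
#' @param ... unused.
#' @return Enhanced matrix (or list of matrices).
#' @export
predict.eat_enhancer <- function(object, newdata, clamp01 = FALSE, ...) {
  one <- function(x) {
    if (inherits(x, "single_view_image")) x <- x$values
    check_matrix(x)
    if (!all(dim(x) == object$config$input_size))
      stop("input dimensions must match the model's input_size",
           call. = FALSE)
    out <- unet_forward(object$weights, object$config, x,
                        training = FALSE)$out
    if (clamp01) out <- pmin(pmax(out, 0), 1)
    out
  }
  if (is.list(newdata) && !inherits(newdata, "single_view_image"))
    lapply(newdata, one) else one(newdata)
}

#' @rdname predict.eat_enhancer
#' @param model a fitted `eat_enhancer`.
#' @param x input image(s), as in `newdata`.
#' @export
enhance <- function(model, x, clamp01 = FALSE) {
  predict(model, x, clamp01 = clamp01)
}

#' @export
plot.eat_enhancer <- function(x, ...) {
  log <- x$training_log
  graphics::matplot(log$epoch, cbind(log$train_loss, log$val_loss),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "DSSIM loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Residual maps of a fitted enhancer
#'
#' @param object a fitted `eat_enhancer`.
#' @param pairs list of `list(x = , y = )` normalized pairs.
#' @param ... unused.
#' @return List of `prediction - target` matrices.
#' @export
residuals.eat_enhancer <- function(object, pairs, ...) {
  lapply(pairs, function(p) predict(object, p$x) - p$y)
}

#' Split datasets into disjoint train/validation/test lists
#'
#' The split is by dataset (electrode configuration), never by view, so no
#' configuration leaks across splits. The shuffle is seeded.
#'
#' @param viewsets list of `viewset` objects (or any list; elements are
#'   assigned whole).
#' @param n_train,n_val,n_test split sizes; their sum must not exceed
#'   `length(viewsets)`.
#' @param seed shuffle seed.
#' @return `list(train = , val = , test = )` of disjoint sublists.
#' @export
split_datasets <- function(viewsets, n_train, n_val, n_test, seed = 1L) {
  n <- length(viewsets)
  n_train <- as.integer(n_train); n_val <- as.integer(n_val)
  n_test <- as.integer(n_test)
  if (any(c(n_train, n_val, n_test) < 0L))
    stop("split sizes must be non-negative", call. = FALSE)
  if (n_train + n_val + n_test > n)
    stop(sprintf("split sizes (%d) exceed the %d available datasets",
                 n_train + n_val + n_test, n), call. = FALSE)
  ord <- with_seed(seed, sample.int(n))
  idx_train <- ord[seq_len(n_train)]
  idx_val <- ord[n_train + seq_len(n_val)]
  idx_test <- ord[n_train + n_val + seq_len(n_test)]
  list(train = viewsets[idx_train], val = viewsets[idx_val],
       test = viewsets[idx_test])
}

#' Turn viewsets into normalized training pairs
#'
#' Each view contributes one pair: the min-max normalized single-view image
#' and the dataset's normalized full-view image, with labels identifying
#' dataset and view angle.
#'
#' @param viewsets list of `viewset` objects.
#' @return `list(pairs = , labels = )`; `pairs` is a list of
#'   `list(x = , y = )`, `labels` a data.frame (`dataset_id`,
#'   `view_angle`).
#' @export
viewset_pairs <- function(viewsets) {
  pairs <- list(); ids <- character(); angs <- numeric()
  for (vs in viewsets) {
    y <- normalize01(vs$full$values, on_constant = "zero")
    for (s in vs$singles) {
      pairs[[length(pairs) + 1L]] <-
        list(x = normalize01(s$values, on_constant = "zero"), y = y)
      ids <- c(ids, vs$dataset_id)
      angs <- c(angs, s$view_angle)
    }
  }
  list(pairs = pairs,
       labels = data.frame(dataset_id = ids, view_angle = angs))
}
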
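#' Min-max normalization to the unit interval
#'
#' All evaluation metrics (and the enhancer's inputs/targets) work on
#' per-image min-max normalized intensities in \[0, 1\].
#'
#' @param image finite numeric matrix.
#' @param on_constant what to do with a constant image: `"error"` (default)
#'   or `"zero"` (return the zero image with a warning, the batch-evaluation
#'   convention).
#' @return Matrix with minimum 0 and maximum 1.
#' @export
normalize01 <- function(image, on_constant = c("error", "zero")) {
  check_matrix(image)
  on_constant <- match.arg(on_constant)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    if (on_constant == "error")
      stop("cannot normalize a constant image", call. = FALSE)
    warning("constant image normalized to all zeros", call. = FALSE)
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - lo) / (hi - lo)
}

check_pair <- function(a, b) {
  check_matrix(a, "a"); check_matrix(b, "b")
  if (!all(dim(a) == dim(b)))
    stop("images must have identical dimensions", call. = FALSE)
}

#' Root-mean-squared error between two normalized images
#' @param a,b numeric matrices of identical dimensions (expected in \[0, 1\]).
#' @return Non-negative scalar.
#' @export
eat_rmse <- function(a, b) {
  check_pair(a, b)
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 * log10(1 / rmse)` with peak value 1 on the normalized scale.
#' Identical images (rmse 0) return the capped sentinel `cap` (default
#' 99 dB) flagged with attribute `capped = TRUE`, so aggregates stay finite.
#'
#' @inheritParams eat_rmse
#' @param cap sentinel/ceiling in dB for vanishing errors.
#' @return Scalar dB value.
#' @export
eat_psnr <- function(a, b, cap = 99) {
  r <- eat_rmse(a, b)
  if (r == 0 || 20 * log10(1 / r) > cap)
    return(structure(cap, capped = TRUE))
  20 * log10(1 / r)
}

# SSIM internals shared with the training loss: Wang et al. constants,
# 11x11 Gaussian window (sigma 1.5, truncate 3.5), population covariance,
# map cropped by the window radius before averaging (making the boundary
# padding mode immaterial).
ssim_fields <- function(a, b, sigma = 1.5, truncate = 3.5,
                        K1 = 0.01, K2 = 0.03, L = 1) {
  k <- gauss_kernel(sigma, truncate)
  r <- (length(k) - 1L) / 2L
  if (nrow(a) < 2 * r + 1 || ncol(a) < 2 * r + 1)
    stop(sprintf("images must be at least %d x %d for SSIM",
                 2 * r + 1, 2 * r + 1), call. = FALSE)
  f <- function(x) cpp_sepconv_same(x, k)
  ux <- f(a); uy <- f(b)
  vx <- f(a * a) - ux^2
  vy <- f(b * b) - uy^2
  vxy <- f(a * b) - ux * uy
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  A1 <- 2 * ux * uy + C1; A2 <- 2 * vxy + C2
  B1 <- ux^2 + uy^2 + C1; B2 <- vx + vy + C2
  S <- (A1 * A2) / (B1 * B2)
  crop <- matrix(FALSE, nrow(a), ncol(a))
  crop[(r + 1):(nrow(a) - r), (r + 1):(ncol(a) - r)] <- TRUE
  list(k = k, r = r, ux = ux, uy = uy, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       S = S, crop = crop, mssim = mean(S[crop]))
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11x11 Gaussian window (sigma 1.5), K1 = 0.01,
#' K2 = 0.03 and dynamic range 1 — the canonical constants. The SSIM map is
#' cropped by the window radius before averaging, so every retained window
#' lies fully inside the image and the result matches reference
#' implementations exactly.
#'
#' @inheritParams eat_rmse
#' @return Scalar in \[-1, 1\].
#' @export
eat_ssim <- function(a, b) {
  check_pair(a, b)
  ssim_fields(a, b)$mssim
}

#' Iso-pressure DICE coefficient
#'
#' Binarizes both normalized images at `level` and returns
#' `2 |A and B| / (|A| + |B|)`. Both masks empty gives 1; exactly one empty
#' gives 0.
#'
#' @inheritParams eat_rmse
#' @param level threshold fraction in (0, 1) on the normalized scale
#'   (equivalently, a percentage of the maximum).
#' @return Scalar in \[0, 1\].
#' @export
dice_iso <- function(a, b, level) {
  check_pair(a, b)
  stopifnot_scalar_num(level, "level")
  if (level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)", call. = FALSE)
  A <- a >= level; B <- b >= level
  na <- sum(A); nb <- sum(B)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  2 * sum(A & B) / (na + nb)
}

#' Evaluate candidate/reference image pairs with the full metric suite
#'
#' Min-max normalizes each image independently (constant images become all
#' zeros with a warning), then computes RMSE, PSNR, SSIM and iso-pressure
#' DICE at the requested levels per pair, plus mean and standard deviation
#' aggregates. The standard deviation uses the population (n) convention so
#' "mean +/- sd" summaries are well defined for any sample count.
#'
#' @param candidates,references lists of numeric matrices, pairwise
#'   identical dimensions.
#' @param labels optional data.frame with one row per pair (e.g.
#'   `dataset_id`, `view_angle`) carried into the per-sample table.
#' @param arm label for this evaluation arm (e.g. `"single_view"` or
#'   `"enhanced"`).
#' @param dice_levels iso-pressure levels, default 10-70 percent.
#' @param psnr_cap sentinel for [eat_psnr()].
#' @return Object of class `metrics_report`: list with `per_sample` and
#'   `aggregate` data.frames.
#' @export
evaluate_pairs <- function(candidates, references, labels = NULL,
                           arm = "candidate",
                           dice_levels = seq(0.1, 0.7, by = 0.1),
                           psnr_cap = 99) {
  if (length(candidates) == 0L)
    stop("`candidates` must be non-empty", call. = FALSE)
  if (length(candidates) != length(references))
    stop("`candidates` and `references` must have equal length", call. = FALSE)
  if (!is.null(labels) && nrow(labels) != length(candidates))
    stop("`labels` must have one row per pair", call. = FALSE)
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    a <- normalize01(candidates[[i]], on_constant = "zero")
    b <- normalize01(references[[i]], on_constant = "zero")
    p <- eat_psnr(a, b, cap = psnr_cap)
    row <- data.frame(arm = arm, sample = i,
                      rmse = eat_rmse(a, b), psnr = as.numeric(p),
                      psnr_capped = isTRUE(attr(p, "capped")),
                      ssim = eat_ssim(a, b))
    for (lv in dice_levels)
      row[[sprintf("dice_%02d", round(100 * lv))]] <- dice_iso(a, b, lv)
    rows[[i]] <- row
  }
  per_sample <- do.call(rbind, rows)
  if (!is.null(labels)) per_sample <- cbind(labels, per_sample)
  structure(list(per_sample = per_sample,
                 aggregate = aggregate_metrics(per_sample)),
            class = "metrics_report")
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

aggregate_metrics <- function(per_sample) {
  cols <- setdiff(names(per_sample),
                  c("arm", "sample", "psnr_capped", "dataset_id",
                    "view_angle"))
  cols <- cols[vapply(per_sample[cols], is.numeric, logical(1))]
  out <- lapply(split(per_sample, per_sample$arm), function(d) {
    data.frame(arm = d$arm[1], metric = cols,
               mean = vapply(cols, function(cn) mean(d[[cn]]), numeric(1)),
               sd = vapply(cols, function(cn) sd_pop(d[[cn]]), numeric(1)),
               n = nrow(d), row.names = NULL)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Merge metric reports from several arms into one
#' @param ... `metrics_report` objects.
#' @return A combined `metrics_report`.
#' @export
merge_reports <- function(...) {
  reports <- list(...)
  per_sample <- do.call(rbind, lapply(reports, `[[`, "per_sample"))
  structure(list(per_sample = per_sample,
                 aggregate = aggregate_metrics(per_sample)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Metrics report (mean +/- population sd per arm)\n")
  agg <- x$aggregate
  for (arm in unique(agg$arm)) {
    cat(sprintf("  arm: %s (n = %d)\n", arm, agg$n[agg$arm == arm][1]))
    d <- agg[agg$arm == arm, ]
    for (k in seq_len(nrow(d)))
      cat(sprintf("    %-8s %s +/- %s\n", d$metric[k],
                  format(d$mean[k], digits = digits),
                  format(d$sd[k], digits = digits)))
  }
  invisible(x)
}

#' Write a metrics report to CSV
#'
#' Emits the per-sample table and the aggregate block (Table-style rows:
#' RMSE, PSNR, SSIM, DICE 10-70 percent) to two CSV files.
#'
#' @param report a `metrics_report`.
#' @param path base path; writes `<path>_per_sample.csv` and
#'   `<path>_aggregate.csv`.
#' @return Invisibly, the two file paths.
#' @export
write_metrics_csv <- function(report, path) {
  p1 <- paste0(path, "_per_sample.csv")
  p2 <- paste0(path, "_aggregate.csv")
  utils::write.csv(report$per_sample, p1, row.names = FALSE)
  utils::write.csv(report$aggregate, p2, row.names = FALSE)
  invisible(c(per_sample = p1, aggregate = p2))
}
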
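#' Experiment configuration for the end-to-end workflow
#'
#' Bundles every stage's parameters: grid, array geometry, phantom sampling
#' bounds, dataset counts and split, network and training configuration,
#' and one global seed from which every stage seed is derived
#' deterministically. Training/validation phantoms draw voltages from
#' `train_voltage_range` and test phantoms from `test_voltage_range`,
#' mirroring the lower-voltage-train / higher-voltage-test protocol.
#'
#' @param grid an [image_grid()].
#' @param geometry an [array_geometry()].
#' @param n_train,n_val,n_test datasets per split.
#' @param n_views views per dataset, equally spaced over 360 degrees.
#' @param train_voltage_range,test_voltage_range V/cm sampling intervals.
#' @param unet a [unet_config()]; its `input_size` must match the grid.
#' @param tc a [train_config()].
#' @param seed global integer seed.
#' @return Object of class `eat_experiment_config`.
#' @export
eat_experiment_config <- function(grid, geometry, n_train, n_val, n_test,
                                  n_views, train_voltage_range = c(1200, 2000),
                                  test_voltage_range = c(2400, 2400),
                                  unet = unet_config(), tc = train_config(),
                                  seed = 1L) {
  if (!all(unet$input_size == c(grid$n_rows, grid$n_cols)))
    stop("unet input_size must match the grid dimensions", call. = FALSE)
  structure(list(grid = grid, geometry = geometry,
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), n_views = as.integer(n_views),
                 train_voltage_range = as.numeric(train_voltage_range),
                 test_voltage_range = as.numeric(test_voltage_range),
                 unet = unet, tc = tc, seed = as.integer(seed)),
            class = "eat_experiment_config")
}

#' Ready-made experiment presets
#'
#' `desk_preset()` is the CPU-scale benchmark used throughout the test
#' suite: 10/2/2 datasets, 16 views, 64 x 64 grid, 16-element array and a
#' reduced U-Net (depth 2, 8 base filters). `paper_preset()` declares the
#' full-scale protocol: 40/6/10 datasets, 60 views, 256 x 256 grid,
#' 128-element array, depth-4 U-Net — sized for hours of compute, provided
#' for completeness.
#'
#' @param seed global seed.
#' @param max_epochs training epochs for the desk preset (default 20).
#' @return An [eat_experiment_config()].
#' @export
desk_preset <- function(seed = 1L, max_epochs = 20L) {
  grid <- image_grid(64L, 64L, spacing = 0.6)
  geometry <- array_geometry(n_elements = 16L, pitch = 4, standoff = 40)
  eat_experiment_config(
    grid = grid, geometry = geometry,
    n_train = 10L, n_val = 2L, n_test = 2L, n_views = 16L,
    unet = unet_config(input_size = c(64L, 64L), depth = 2L,
                       base_filters = 8L),
    tc = train_config(max_epochs = max_epochs, seed = seed),
    seed = seed)
}

#' @rdname desk_preset
#' @export
paper_preset <- function(seed = 1L) {
  eat_experiment_config(
    grid = image_grid(256L, 256L, spacing = 0.15),
    geometry = array_geometry(),
    n_train = 40L, n_val = 6L, n_test = 10L, n_views = 60L,
    unet = unet_config(), tc = train_config(max_epochs = 100L, seed = seed),
    seed = seed)
}

#' Run the complete simulate-train-evaluate pipeline
#'
#' Generates phantom datasets (training/validation at the lower voltage
#' range, test at the higher), builds all views, splits strictly by
#' dataset, trains the enhancer, enhances the held-out test views, and
#' evaluates both arms — raw single-view and enhanced — against the
#' full-view ground truth. Every stage is seeded from the global seed, so
#' reruns with the same configuration reproduce the report exactly.
#'
#' @param config an [eat_experiment_config()].
#' @param out_dir optional directory; when given, the container, model
#'   checkpoint, training log and CSV report are written there along with a
#'   manifest recording the configuration.
#' @param verbose print stage progress.
#' @return List with `report` (a `metrics_report` with arms
#'   `"single_view"` and `"enhanced"`), `model`, `splits` (dataset ids per
#'   split), `viewsets` and `paths` (when `out_dir` is given).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "eat_experiment_config"))
  say <- function(fmt, ...) if (verbose)
    message(sprintf("[eatomo %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  t0 <- Sys.time()

  # --- stage 1: dataset generation -----------------------------------------
  n_lower <- config$n_train + config$n_val
  say("generating %d train/val datasets (%g-%g V/cm) and %d test (%g-%g V/cm), %d views each",
      n_lower, config$train_voltage_range[1], config$train_voltage_range[2],
      config$n_test, config$test_voltage_range[1],
      config$test_voltage_range[2], config$n_views)
  make_set <- function(k, vrange, tag) {
    cfg <- sample_config(derive_seed(config$seed, k), vrange, config$grid)
    build_viewset(cfg, config$geometry, config$grid, config$n_views,
                  dataset_id = sprintf("%s_%02d", tag, k))
  }
  lower <- lapply(seq_len(n_lower), make_set,
                  vrange = config$train_voltage_range, tag = "lo")
  test_sets <- lapply(n_lower + seq_len(config$n_test), make_set,
                      vrange = config$test_voltage_range, tag = "hi")

  # --- stage 2: split by dataset -------------------------------------------
  sp <- split_datasets(lower, config$n_train, config$n_val, 0L,
                       seed = derive_seed(config$seed, 9001L))
  splits <- list(train = vapply(sp$train, `[[`, "", "dataset_id"),
                 val = vapply(sp$val, `[[`, "", "dataset_id"),
                 test = vapply(test_sets, `[[`, "", "dataset_id"))
  say("split by dataset: %d train / %d val / %d test",
      length(sp$train), length(sp$val), length(test_sets))

  # --- stage 3: training ----------------------------------------------------
  tr <- viewset_pairs(sp$train)
  va <- viewset_pairs(sp$val)
  say("training U-Net (depth %d, base %d) on %d pairs, %d epochs",
      config$unet$depth, config$unet$base_filters, length(tr$pairs),
      config$tc$max_epochs)
  model <- train_enhancer(tr$pairs, va$pairs, config$unet, config$tc,
                          verbose = verbose)
  say("best checkpoint at epoch %d (val DSSIM %.4f)", model$best_epoch,
      model$training_log$val_loss[model$best_epoch])

  # --- stage 4: enhancement + evaluation -----------------------------------
  te <- viewset_pairs(test_sets)
  say("enhancing and evaluating %d held-out test views", length(te$pairs))
  singles <- lapply(te$pairs, `[[`, "x")
  fulls <- lapply(te$pairs, `[[`, "y")
  enhanced <- lapply(singles, function(x) predict(model, x, clamp01 = TRUE))
  rep_single <- evaluate_pairs(singles, fulls, labels = te$labels,
                               arm = "single_view")
  rep_enh <- evaluate_pairs(enhanced, fulls, labels = te$labels,
                            arm = "enhanced")
  report <- merge_reports(rep_single, rep_enh)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    container <- file.path(out_dir, "container")
    save_container(c(lower, test_sets), container)
    ckpt <- file.path(out_dir, "enhancer.rds")
    saveRDS(model, ckpt)
    csv <- write_metrics_csv(report, file.path(out_dir, "metrics"))
    log_csv <- file.path(out_dir, "training_log.csv")
    utils::write.csv(model$training_log, log_csv, row.names = FALSE)
    manifest <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(
      list(seed = config$seed, splits = splits,
           config = serialize_config(config),
           package_version = as.character(utils::packageVersion("eatomo")),
           r_version = R.version.string,
           finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths <- list(container = container, checkpoint = ckpt,
                  metrics = unname(csv), training_log = log_csv,
                  manifest = manifest)
  }
  say("pipeline finished in %.1f s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  list(report = report, model = model, splits = splits,
       viewsets = list(lower = lower, test = test_sets), paths = paths)
}

serialize_config <- function(config) {
  list(grid = unclass(config$grid), geometry = unclass(config$geometry),
       n_train = config$n_train, n_val = config$n_val,
       n_test = config$n_test, n_views = config$n_views,
       train_voltage_range = config$train_voltage_range,
       test_voltage_range = config$test_voltage_range,
       unet = unclass(config$unet), tc = unclass(config$tc),
       seed = config$seed)
}
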
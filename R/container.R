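# On-disk container for simulated acquisitions. A container is a directory:
#
#   <path>/manifest.json                 schema version, counts, metadata
#   <path>/datasets/<id>/config.json     electrode configuration
#   <path>/datasets/<id>/grid.json       image grid
#   <path>/datasets/<id>/geometry.json   array geometry
#   <path>/datasets/<id>/source.rds      phantom map (matrix)
#   <path>/datasets/<id>/views/view_<k>.rds  list(gram, angle, single)
#   <path>/datasets/<id>/full.rds        full-view composite (matrix)
#
# Arrays are serialized with saveRDS (version 3), giving bit-exact
# round-trips; attributes (angles, geometry) live in the JSON sidecars and
# view files. The schema version is checked on load.

CONTAINER_SCHEMA <- "eatomo-container-1"

#' Save view sets to an on-disk container
#'
#' @param viewsets list of `viewset` objects.
#' @param path directory to create (must not be an existing non-container
#'   file).
#' @return Invisibly, `path`.
#' @export
save_container <- function(viewsets, path) {
  if (length(viewsets) == 0L)
    stop("`viewsets` must be non-empty", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(viewsets, function(v) v$dataset_id, character(1))
  if (anyDuplicated(ids)) stop("dataset ids must be unique", call. = FALSE)
  manifest <- list(schema = CONTAINER_SCHEMA,
                   n_datasets = length(viewsets), dataset_ids = ids,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   package_version = as.character(
                     utils::packageVersion("eatomo")))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (vs in viewsets) {
    d <- file.path(path, "datasets", vs$dataset_id)
    dir.create(file.path(d, "views"), showWarnings = FALSE, recursive = TRUE)
    cfg <- vs$config
    jsonlite::write_json(
      list(tip_a = cfg$tip_a, tip_b = cfg$tip_b, voltage = cfg$voltage,
           tip_sigma = cfg$tip_sigma, echo_amplitude = cfg$echo_amplitude,
           seed = cfg$seed),
      file.path(d, "config.json"), auto_unbox = TRUE, digits = NA)
    g <- vs$full$grid
    jsonlite::write_json(unclass(g), file.path(d, "grid.json"),
                         auto_unbox = TRUE, digits = NA)
    geo <- vs$grams[[1]]$geometry
    jsonlite::write_json(unclass(geo), file.path(d, "geometry.json"),
                         auto_unbox = TRUE, digits = NA)
    saveRDS(vs$source$values, file.path(d, "source.rds"))
    for (k in seq_along(vs$grams)) {
      saveRDS(list(gram = vs$grams[[k]]$values,
                   angle = vs$grams[[k]]$view_angle,
                   single = vs$singles[[k]]$values),
              file.path(d, "views", sprintf("view_%03d.rds", k - 1L)))
    }
    saveRDS(vs$full$values, file.path(d, "full.rds"))
  }
  invisible(path)
}

#' Load view sets from an on-disk container
#'
#' @param path container directory written by [save_container()].
#' @return List of `viewset` objects.
#' @export
load_container <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path))
    stop(sprintf("not a container: missing %s", mf_path), call. = FALSE)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(manifest$schema, CONTAINER_SCHEMA))
    stop(sprintf("incompatible container schema '%s' (expected '%s')",
                 manifest$schema %||% "<missing>", CONTAINER_SCHEMA),
         call. = FALSE)
  lapply(manifest$dataset_ids, function(id) {
    d <- file.path(path, "datasets", id)
    for (part in c("config.json", "grid.json", "geometry.json",
                   "source.rds", "full.rds"))
      if (!file.exists(file.path(d, part)))
        stop(sprintf("container dataset '%s' is missing '%s'", id, part),
             call. = FALSE)
    gl <- jsonlite::read_json(file.path(d, "grid.json"),
                              simplifyVector = TRUE)
    grid <- image_grid(gl$n_rows, gl$n_cols, gl$spacing, gl$origin,
                       gl$rotation_center)
    ge <- jsonlite::read_json(file.path(d, "geometry.json"),
                              simplifyVector = TRUE)
    nz <- function(x) if (length(x) == 0L) NULL else x
    geometry <- array_geometry(ge$n_elements, ge$pitch, ge$standoff,
                               ge$sound_speed, ge$sampling_rate,
                               nz(ge$n_samples), nz(ge$quantization_bits),
                               isTRUE(ge$time_filter))
    cf <- jsonlite::read_json(file.path(d, "config.json"),
                              simplifyVector = TRUE)
    config <- electrode_config(cf$tip_a, cf$tip_b, cf$voltage, cf$tip_sigma,
                               cf$echo_amplitude, cf$seed)
    source <- pressure_source_map(readRDS(file.path(d, "source.rds")), grid)
    vfiles <- sort(list.files(file.path(d, "views"), pattern = "^view_",
                              full.names = TRUE))
    if (length(vfiles) == 0L)
      stop(sprintf("container dataset '%s' has no view groups", id),
           call. = FALSE)
    grams <- list(); singles <- list(); angles <- numeric()
    for (vf in vfiles) {
      v <- readRDS(vf)
      grams[[length(grams) + 1L]] <- channel_gram(v$gram, v$angle, geometry)
      singles[[length(singles) + 1L]] <-
        single_view_image(v$single, v$angle, grid)
      angles <- c(angles, v$angle)
    }
    full_values <- readRDS(file.path(d, "full.rds"))
    full <- structure(list(values = full_values, n_views = length(grams),
                           grid = grid), class = "full_view_image")
    structure(list(dataset_id = id, config = config, source = source,
                   grams = grams, singles = singles, full = full,
                   angles = angles), class = "viewset")
  })
}
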
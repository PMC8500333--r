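sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a calibrated image stack as multi-page TIFF
#'
#' Pages are stored frame-major (`(t, c)` page order) at 32-bit depth, with
#' a JSON sidecar carrying the calibration (pixel size, frame interval,
#' channel names), the axis order and an exactly invertible power-of-two
#' intensity scaling (the TIFF container only stores values in `[0, 1]`).
#' Writing quantizes intensities to the container's 32-bit grid, so a
#' round trip reproduces the data to a relative error below 2^-31
#' (~5 x 10^-10) of the stack's dynamic range; calibration metadata round
#' trips exactly.
#' Reading without the sidecar (or one lacking the calibration) is an error:
#' silent pixel units are never returned. Sidecars declaring a permuted axis
#' order are reshuffled to the canonical T x C x Y x X on read.
#'
#' @param stack An [image_stack()].
#' @param path Output `.tif` path; the sidecar is written next to it.
#' @return `write_image_stack`: the path, invisibly. `read_image_stack`: an
#'   [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  lo <- min(stack$data, 0, na.rm = TRUE)
  hi <- max(stack$data - lo, na.rm = TRUE)
  scale <- if (hi > 1) 2^ceiling(log2(hi)) else 1
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      pages[[k]] <- (stack$data[t, ch, , ] - lo) / scale
      k <- k + 1L
    }
  }
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  meta <- list(
    axes = "TCYX", shape = as.integer(d),
    pixel_size_um = stack$pixel_size_um,
    frame_interval_s = stack$frame_interval_s,
    channel_names = stack$channel_names,
    intensity_offset = lo, intensity_scale = scale
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort("image stack has no metadata sidecar: calibration unknown.")
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("pixel_size_um", "frame_interval_s", "shape", "axes")) {
    if (is.null(meta[[f]])) abort(sprintf("sidecar lacks required field `%s`.", f))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  axes <- strsplit(meta$axes, "")[[1]]
  shape <- as.integer(meta$shape)
  if (length(axes) != 4 || !setequal(axes, c("T", "C", "Y", "X"))) {
    abort("sidecar `axes` must be a permutation of TCYX.")
  }
  names(shape) <- axes
  nt <- shape[["T"]]; nc <- shape[["C"]]
  if (length(pages) != nt * nc) {
    abort(sprintf("dimension mismatch: %d pages on disk, %d declared.",
                  length(pages), nt * nc))
  }
  # pages are stored in row-major order of the two leading declared axes
  lead <- axes[1:2]
  arr <- array(0, dim = c(nt, nc, shape[["Y"]], shape[["X"]]))
  k <- 1L
  for (a in seq_len(shape[[lead[1]]])) {
    for (b in seq_len(shape[[lead[2]]])) {
      pg <- pages[[k]]
      if (!all(dim(pg) == c(shape[["Y"]], shape[["X"]]))) {
        abort("dimension mismatch between page size and declared Y/X shape.")
      }
      t_idx <- if (lead[1] == "T") a else b
      c_idx <- if (lead[1] == "C") a else b
      arr[t_idx, c_idx, , ] <- pg
      k <- k + 1L
    }
  }
  off <- meta$intensity_offset %||% 0
  scl <- meta$intensity_scale %||% 1
  image_stack(arr * scl + off,
              pixel_size_um = meta$pixel_size_um,
              frame_interval_s = meta$frame_interval_s,
              channel_names = meta$channel_names)
}

#' Read comet trajectories from a tracker CSV
#'
#' Reads the `track_id, frame, time_s, x_um[, y_um]` dialect produced by
#' common kymograph trackers. A malformed numeric field or a missing
#' required column is an error naming the offending line.
#'
#' @param path CSV path with header row.
#' @return Tibble of trajectories, ordered by track and time.
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  need <- c("track_id", "frame", "time_s", "x_um")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed row(s) at line(s) %s of %s.",
                  paste(unique(probs$row + 1L), collapse = ", "), path))
  }
  num <- c("frame", "time_s", "x_um", intersect("y_um", names(df)))
  for (cn in num) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))) & !is.na(df[[cn]]))
      abort(sprintf("non-numeric value in column `%s` at data line(s) %s.",
                    cn, paste(bad + 1L, collapse = ", ")))
    }
  }
  dplyr::arrange(as_tibble(df), .data$track_id, .data$time_s)
}

#' Write comet trajectories to CSV
#'
#' @param tracks Trajectory tibble (see [read_tracks_csv()] for the dialect).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  assert_tracks(tracks)
  readr::write_csv(tracks, path, progress = FALSE)
  invisible(path)
}

#' Write / read an analysis result record as JSON
#'
#' Results carry provenance: the configuration hash, the seed and the
#' package version, so every emitted number is traceable to the run that
#' produced it.
#'
#' @param results Named list (or tibble) of results.
#' @param path Output `.json` path.
#' @param config Optional configuration object hashed into the provenance.
#' @param seed Optional seed recorded in the provenance.
#' @return `write_results`: the path, invisibly. `read_results`: the record
#'   as a list.
#' @export
write_results <- function(results, path, config = NULL, seed = NULL) {
  rec <- list(
    provenance = list(
      package = "midzone",
      version = as.character(utils::packageVersion("midzone")),
      config_hash = if (is.null(config)) NA else rlang::hash(config),
      seed = seed
    ),
    results = results
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Serialize / deserialize a simulation configuration as YAML
#'
#' Round trips a [spindle_sim_config()] losslessly through YAML. Unknown
#' keys in the file are rejected, so typos can not silently fall back to
#' defaults.
#'
#' @param config A `spindle_sim_config`.
#' @param path YAML path.
#' @return `write_spindle_config`: the path, invisibly.
#'   `read_spindle_config`: a validated `spindle_sim_config`.
#' @export
write_spindle_config <- function(config, path) {
  stopifnot(inherits(config, "spindle_sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_spindle_config
#' @export
read_spindle_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(spindle_sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  do.call(spindle_sim_config, vals)
}
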
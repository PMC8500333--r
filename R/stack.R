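#' Calibrated image stack
#'
#' Container for a calibrated T x C x Y x X intensity movie. All analysis
#' functions require physical calibration; a stack can not be built without
#' pixel size and frame interval.
#'
#' @param data Numeric array, dimensions T x C x Y x X.
#' @param pixel_size_um Pixel size (um/pixel, > 0).
#' @param frame_interval_s Frame interval (s, > 0).
#' @param channel_names Character vector, one name per channel.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, pixel_size_um, frame_interval_s,
                        channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 4) {
    abort("`data` must be a 4-d array (T x C x Y x X).")
  }
  if (any(dim(data) < 1)) abort("all stack dimensions must be >= 1.")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.")
  }
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1 ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0) {
    abort("`frame_interval_s` must be a single positive number.")
  }
  nc <- dim(data)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    abort("`channel_names` must have one entry per channel.")
  }
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channel_names = channel_names),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames x %d channels x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel size %.4g um, frame interval %.4g s, channels: %s\n",
              x$pixel_size_um, x$frame_interval_s,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Kymograph container
#'
#' A per-channel time x axial-position intensity map generated along the
#' spindle pole-to-pole axis. The axial coordinate is signed, in um, with 0 at
#' the spindle midpoint.
#'
#' @param data Named list of T x X numeric matrices, one per channel.
#' @param x_um Axial positions of the columns (um, 0 at the spindle midpoint).
#' @param frame_interval_s Frame interval (s).
#' @param pixel_size_um Axial calibration (um/column).
#' @param onset_frame 0-based anaphase-onset frame index, or `NULL`.
#' @param metaphase_pole_distance_um Mean pre-onset pole distance (um), or
#'   `NULL`.
#' @return A `kymograph` object.
#' @export
kymograph <- function(data, x_um, frame_interval_s, pixel_size_um,
                      onset_frame = NULL, metaphase_pole_distance_um = NULL) {
  if (!is.list(data) || is.null(names(data)) ||
      !all(vapply(data, is.matrix, TRUE))) {
    abort("`data` must be a named list of T x X matrices.")
  }
  nx <- unique(vapply(data, ncol, 1L))
  nt <- unique(vapply(data, nrow, 1L))
  if (length(nx) != 1 || length(nt) != 1) {
    abort("all channels must share the same dimensions.")
  }
  if (length(x_um) != nx) abort("`x_um` must have one entry per column.")
  if (!is.null(onset_frame) && !is.na(onset_frame) &&
      (onset_frame < 0 || onset_frame >= nt)) {
    abort("`onset_frame` must lie within [0, T).")
  }
  structure(list(data = data, x_um = as.numeric(x_um),
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um,
                 onset_frame = onset_frame,
                 metaphase_pole_distance_um = metaphase_pole_distance_um),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d columns, channels: %s\n",
              nrow(x$data[[1]]), ncol(x$data[[1]]),
              paste(names(x$data), collapse = ", ")))
  if (!is.null(x$onset_frame)) {
    cat(sprintf("  anaphase onset at frame %d\n", x$onset_frame))
  }
  if (!is.null(x$metaphase_pole_distance_um)) {
    cat(sprintf("  metaphase pole distance %.2f um\n",
                x$metaphase_pole_distance_um))
  }
  invisible(x)
}

#' @describeIn kymograph Long-format view: one row per (frame, column,
#'   channel) with `time_s`, `x_um`, `intensity`.
#' @param x,... Kymograph and ignored arguments (tibble generic).
#' @method as_tibble kymograph
#' @export
as_tibble.kymograph <- function(x, ...) {
  purrr::imap_dfr(x$data, function(m, ch) {
    tibble(
      channel = ch,
      frame = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
      time_s = rep((seq_len(nrow(m)) - 1L) * x$frame_interval_s, times = ncol(m)),
      x_um = rep(x$x_um, each = nrow(m)),
      intensity = as.vector(m)
    )
  })
}
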
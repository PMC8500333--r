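assert_tracks <- function(tracks) {
  need <- c("track_id", "time_s", "x_um")
  if (!is.data.frame(tracks) || !all(need %in% names(tracks))) {
    abort("tracks need columns `track_id`, `time_s`, `x_um`.")
  }
  tracks
}

#' Filter comet tracks by minimum length
#'
#' Removes tracks with fewer than `min_frames` samples, the same rule the
#' external tracker applies ("minimum number of consecutive frames" = 3);
#' the boundary is inclusive. The number of removed tracks is reported via
#' attribute `n_removed` and a message.
#'
#' @param tracks Tibble `track_id`, `time_s`, `x_um` (plus any extra
#'   columns).
#' @param min_frames Minimum samples per track (inclusive).
#' @return Filtered tibble with attribute `n_removed`.
#' @export
filter_tracks <- function(tracks, min_frames = 3) {
  tracks <- assert_tracks(tracks)
  keep <- tracks |>
    dplyr::count(.data$track_id) |>
    dplyr::filter(.data$n >= min_frames) |>
    dplyr::pull(.data$track_id)
  removed <- length(unique(tracks$track_id)) - length(keep)
  out <- dplyr::filter(tracks, .data$track_id %in% keep)
  if (removed > 0) {
    rlang::inform(sprintf("filter_tracks: removed %d track(s) shorter than %d frames.",
                          removed, min_frames))
  }
  attr(out, "n_removed") <- removed
  out
}

#' Average comet speed per track
#'
#' Speed is the Euclidean distance between the first and the last sample of
#' a trajectory divided by the elapsed time (endpoint definition: a track
#' returning to its start has speed zero). Uses `y_um` too when present.
#'
#' @param tracks Tibble `track_id`, `time_s`, `x_um` (optional `y_um`).
#' @return Tibble `track_id`, `duration_s`, `n_frames`, `speed_um_per_s`.
#' @export
comet_speeds <- function(tracks) {
  tracks <- assert_tracks(tracks)
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::summarise(
      duration_s = dplyr::last(.data$time_s) - dplyr::first(.data$time_s),
      n_frames = dplyr::n(),
      dx = dplyr::last(.data$x_um) - dplyr::first(.data$x_um),
      dy = if ("y_um" %in% names(tracks)) {
        dplyr::last(.data$y_um) - dplyr::first(.data$y_um)
      } else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(speed_um_per_s = {
      if (any(.data$duration_s <= 0)) {
        abort("track with zero elapsed time: cannot compute a speed.")
      }
      sqrt(.data$dx^2 + .data$dy^2) / .data$duration_s
    }) |>
    dplyr::select(-"dx", -"dy")
}

#' Classify comets as internal or external
#'
#' A comet is internal when the majority of its samples lie strictly between
#' the axial pole coordinates (a plus end growing within the spindle body),
#' else external (astral).
#'
#' @param tracks Tibble `track_id`, `time_s`, `x_um`.
#' @param pole_positions Numeric `c(p1, p2)` axial pole positions (um).
#' @return Tibble `track_id`, `n_inside`, `n_samples`, `class`.
#' @export
classify_comets <- function(tracks, pole_positions) {
  tracks <- assert_tracks(tracks)
  stopifnot(length(pole_positions) == 2)
  p1 <- min(pole_positions); p2 <- max(pole_positions)
  if (p1 == p2) abort("pole positions must be distinct.")
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_inside = sum(.data$x_um > p1 & .data$x_um < p2),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(class = ifelse(.data$n_inside > .data$n_samples / 2,
                                 "internal", "external"))
}

#' Per-stage comet speed statistics
#'
#' Median speed with the standard error of the mean (the published pairing),
#' plus mean, SD, quartiles and a median-absolute-deviation alternative, per
#' stage. Empty stages are dropped with a warning.
#'
#' @param tracks Tibble with a `stage` column (or supply a single implicit
#'   stage) plus `track_id`, `time_s`, `x_um`.
#' @param stage_levels Optional ordering of stages in the output.
#' @return Tibble, one row per stage: `n_tracks`, `median_speed`,
#'   `mean_speed`, `sd_speed`, `sem_speed`, `mad_speed`, `q25`, `q75`
#'   (um/s).
#' @export
summarize_speeds <- function(tracks, stage_levels = NULL) {
  tracks <- assert_tracks(tracks)
  if (!"stage" %in% names(tracks)) tracks$stage <- "all"
  empty <- setdiff(stage_levels %||% character(), unique(tracks$stage))
  if (length(empty) > 0) {
    warn(sprintf("stages with no tracks omitted: %s", paste(empty, collapse = ", ")))
  }
  sp <- tracks |>
    dplyr::group_by(.data$stage) |>
    dplyr::group_modify(~ comet_speeds(.x)) |>
    dplyr::ungroup()
  out <- sp |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(
      n_tracks = dplyr::n(),
      median_speed = median(.data$speed_um_per_s),
      mean_speed = mean(.data$speed_um_per_s),
      sd_speed = ifelse(dplyr::n() > 1, sd(.data$speed_um_per_s), 0),
      sem_speed = ifelse(dplyr::n() > 1,
                         sd(.data$speed_um_per_s) / sqrt(dplyr::n()), 0),
      mad_speed = stats::mad(.data$speed_um_per_s),
      q25 = unname(quantile(.data$speed_um_per_s, 0.25)),
      q75 = unname(quantile(.data$speed_um_per_s, 0.75)),
      .groups = "drop"
    )
  if (!is.null(stage_levels)) {
    out <- out[order(match(out$stage, stage_levels)), ]
  }
  out
}

#' Survival curve of comet track durations
#'
#' `S(t)` = fraction of tracks whose duration is at least `t`, reported both
#' in seconds and in frames. The curve starts at 1 and is non-increasing.
#'
#' @param tracks Tibble `track_id`, `time_s`, `x_um`.
#' @param frame_interval_s Frame interval used to express durations in
#'   frames; inferred from the data when `NULL`.
#' @return Tibble `duration_s`, `duration_frames`, `survival`, evaluated at
#'   0 and every observed duration.
#' @export
survival_curve <- function(tracks, frame_interval_s = NULL) {
  tracks <- assert_tracks(tracks)
  d <- comet_speeds(tracks)$duration_s
  if (is.null(frame_interval_s)) {
    dt <- tracks |>
      dplyr::group_by(.data$track_id) |>
      dplyr::summarise(dt = min(diff(sort(.data$time_s))), .groups = "drop")
    frame_interval_s <- median(dt$dt)
  }
  ts <- sort(unique(c(0, d)))
  tibble(
    duration_s = ts,
    duration_frames = ts / frame_interval_s,
    survival = vapply(ts, function(t) mean(d >= t), 1)
  )
}

#' Histogram of comet positions along the pole-to-pole axis
#'
#' Maps every comet sample to the normalized pole-to-pole coordinate
#' (`0` = one pole, `1` = the other) and bins the in-range samples. Samples
#' outside the poles (astral comets) are counted separately in `n_outside`.
#'
#' @param tracks Tibble `track_id`, `time_s`, `x_um`.
#' @param pole_positions Numeric `c(p1, p2)` (um).
#' @param bins Number of equal-width bins on `[0, 1]`.
#' @return Tibble `bin_mid`, `bin_lo`, `bin_hi`, `count`; attributes
#'   `n_outside` and `n_samples`.
#' @export
position_histogram <- function(tracks, pole_positions, bins = 20) {
  tracks <- assert_tracks(tracks)
  stopifnot(length(pole_positions) == 2, bins >= 1)
  p1 <- min(pole_positions); p2 <- max(pole_positions)
  if (p1 == p2) abort("pole positions must be distinct.")
  u <- (tracks$x_um - p1) / (p2 - p1)
  inside <- u >= 0 & u <= 1
  br <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(findInterval(u[inside], br, rightmost.closed = TRUE), bins)
  counts <- tabulate(idx, nbins = bins)
  out <- tibble(bin_lo = br[-length(br)], bin_hi = br[-1],
                bin_mid = (br[-length(br)] + br[-1]) / 2, count = counts)
  attr(out, "n_outside") <- sum(!inside)
  attr(out, "n_samples") <- length(u)
  out
}
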
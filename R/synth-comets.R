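#' Typical plus-end comet speeds per mitotic stage
#'
#' Default generator speeds for growing microtubule plus-end comets. The
#' published comparison is graphical, so these defaults encode the field's
#' typical RPE1 values: ~0.33 um/s microtubule growth in metaphase slowing by
#' roughly 30% towards telophase, which reproduces the qualitative decrease
#' from metaphase to late anaphase that the comet pipeline must recover.
#'
#' @return Tibble: `stage`, `speed_um_per_s`, `speed_sd_um_per_s`.
#' @export
comet_stage_presets <- function() {
  tibble(
    stage = c("metaphase", "early_anaphase", "mid_anaphase", "late_anaphase",
              "telophase"),
    speed_um_per_s = c(0.33, 0.30, 0.26, 0.20, 0.18),
    speed_sd_um_per_s = 0.05
  )
}

#' Simulate plus-end comet trajectories
#'
#' Constant-velocity tracks sampled at the frame interval. Per-track speeds
#' are Gaussian around the stage speed (truncated at zero), directions are
#' random, nucleation positions are uniform between the poles for internal
#' comets and outside them (astral) for external comets, and track durations
#' are geometric (the discrete exponential of a constant per-frame end
#' probability) with mean about `mean_duration_s`, floored at `min_frames`
#' samples.
#'
#' @param speed_um_per_s Stage mean comet speed (um/s, >= 0).
#' @param speed_sd_um_per_s SD of per-track speeds (um/s).
#' @param n_tracks Number of tracks.
#' @param mean_duration_s Mean track duration (s).
#' @param frame_interval_s Sampling interval (s).
#' @param pole_positions Numeric `c(p1, p2)` axial pole positions (um),
#'   distinct.
#' @param internal_fraction Fraction of tracks nucleating between the poles.
#' @param astral_extent_um How far beyond a pole external comets may
#'   nucleate (um).
#' @param min_frames Minimum samples per generated track.
#' @param seed Master seed.
#' @return A `comet_sim` list: `tracks` — tibble `track_id`, `frame`,
#'   `time_s`, `x_um` — and `truth` — per-track `speed_um_per_s`, `class`
#'   (`internal`/`external`), `duration_s`.
#' @export
generate_comet_tracks <- function(speed_um_per_s, speed_sd_um_per_s = 0.05,
                                  n_tracks = 50, mean_duration_s = 8,
                                  frame_interval_s = 0.25,
                                  pole_positions = c(-10, 10),
                                  internal_fraction = 0.8,
                                  astral_extent_um = 5,
                                  min_frames = 3, seed = 1L) {
  stopifnot(speed_um_per_s >= 0, speed_sd_um_per_s >= 0, n_tracks >= 1,
            frame_interval_s > 0, length(pole_positions) == 2)
  p1 <- min(pole_positions); p2 <- max(pole_positions)
  if (p1 == p2) abort("pole positions must be distinct.")
  seeds <- derive_seeds(seed, n_tracks)
  pieces <- purrr::map(seq_len(n_tracks), function(j) {
    with_seed(seeds[j], {
      v <- max(rnorm(1, speed_um_per_s, speed_sd_um_per_s), 0)
      internal <- runif(1) < internal_fraction
      dir <- sample(c(-1, 1), 1)
      x0 <- if (internal) runif(1, p1, p2) else {
        side <- sample(c(-1, 1), 1)
        if (side < 0) runif(1, p1 - astral_extent_um, p1)
        else runif(1, p2, p2 + astral_extent_um)
      }
      p_end <- min(frame_interval_s / mean_duration_s, 0.9)
      n <- max(min_frames, 2L + stats::rgeom(1, p_end))
      t <- (seq_len(n) - 1) * frame_interval_s
      list(
        track = tibble(track_id = j, frame = seq_len(n) - 1L, time_s = t,
                       x_um = x0 + dir * v * t),
        truth = tibble(track_id = j, speed_um_per_s = v,
                       class = if (internal) "internal" else "external",
                       duration_s = max(t))
      )
    })
  })
  structure(list(tracks = dplyr::bind_rows(purrr::map(pieces, "track")),
                 truth = dplyr::bind_rows(purrr::map(pieces, "truth"))),
            class = "comet_sim")
}
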
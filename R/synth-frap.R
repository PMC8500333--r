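#' Published midzone-protein FRAP kinetics used as simulation ground truth
#'
#' Recovery time and recovery fraction of the three midzone proteins at each
#' mitotic stage, as measured in gene-edited RPE1 cells: PRC1 recovery times
#' of 6, 11, 11, 44 and 124 s from metaphase to telophase with the recovery
#' fraction falling from 0.55 to 0.27; KIF4A 5.9 s (late anaphase) to 30 s
#' (telophase) with fractions 0.95 to 0.71; CLASP1 in the 1.3-2.9 s range
#' with fractions 0.64-0.79. Only the endpoints of the PRC1 fraction series
#' and of the CLASP1 ranges are published; intermediate stages are linear
#' interpolations between them (flagged by `interpolated`). `n_cells` are the
#' published per-condition cell counts. These values parameterize
#' [generate_frap_curves()] so that the fitting pipeline can be validated by
#' parameter recovery.
#'
#' @return Tibble: `protein`, `stage`, `tau_s`, `mf`, `n_cells`,
#'   `bleach_correct` (whether the reference-region correction is applied for
#'   that protein), `interpolated`.
#' @export
frap_stage_presets <- function() {
  tibble(
    protein = c(rep("PRC1", 5), rep("KIF4A", 2), rep("CLASP1", 4)),
    stage = c("metaphase", "early_anaphase", "mid_anaphase", "late_anaphase",
              "telophase",
              "late_anaphase", "telophase",
              "early_anaphase", "mid_anaphase", "late_anaphase", "telophase"),
    tau_s = c(6, 11, 11, 44, 124, 5.9, 30, 1.3, 1.8333, 2.3667, 2.9),
    mf = c(0.55, 0.48, 0.41, 0.34, 0.27, 0.95, 0.71, 0.79, 0.74, 0.69, 0.64),
    n_cells = c(15L, 15L, 15L, 15L, 15L, 14L, 18L, 9L, 10L, 11L, 8L),
    bleach_correct = c(rep(FALSE, 5), rep(TRUE, 2), rep(TRUE, 4)),
    interpolated = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                     FALSE, TRUE, TRUE, FALSE)
  )
}

#' Simulate an ensemble of FRAP recovery curves
#'
#' Generates `n_curves` raw-intensity FRAP records following the
#' mono-exponential recovery model `I(t) = I0 + Ia (1 - exp(-t / tau))` with
#' `Ia = mf * (1 - I0)`, plus i.i.d. Gaussian noise. Each record has
#' `n_prebleach` pre-bleach frames near the (per-curve, random) intensity
#' scale, a bleach-frame drop to about `I0`, and a recovery sampled every
#' `frame_interval_s` for `duration_s`. Time zero of the recovery model is
#' the first post-bleach frame. An optional global acquisition-bleaching
#' factor `exp(-bleach_rate_per_s t)` multiplies both the region of interest
#' and the co-recorded reference region, which is how the reference-division
#' correction is exercised.
#'
#' @param tau_s Recovery time (s, > 0).
#' @param mf Recovery (mobile) fraction in `[0, 1]`.
#' @param i0 Normalized intensity immediately after the bleach, in `[0, 1)`.
#' @param n_curves Number of cells/curves.
#' @param frame_interval_s Sampling interval (s); 2 s mirrors acquisition at
#'   30 frames per minute.
#' @param duration_s Post-bleach observation window (s); 3 min by default.
#' @param n_prebleach Pre-bleach frames (>= 4, needed for normalization).
#' @param noise_sd Gaussian noise SD on the normalized intensity scale.
#' @param bleach_rate_per_s Acquisition photobleaching rate (1/s).
#' @param seed Master seed.
#' @return A `frap_sim` list: `curves` — tibble `curve_id`, `time_s`,
#'   `phase` (`pre`/`bleach`/`post`), `roi`, `reference` (raw intensities) —
#'   and `truth` — one row per curve with `i0`, `ia`, `tau_s`, `mf`, `scale`.
#' @export
generate_frap_curves <- function(tau_s, mf, i0 = 0.25, n_curves = 15,
                                 frame_interval_s = 2, duration_s = 180,
                                 n_prebleach = 5, noise_sd = 0.02,
                                 bleach_rate_per_s = 0, seed = 1L) {
  stopifnot(tau_s > 0, mf >= 0, i0 >= 0, i0 < 1,
            frame_interval_s > 0, duration_s > frame_interval_s,
            n_prebleach >= 4, n_curves >= 1)
  ia <- mf * (1 - i0)
  if (ia + i0 > 1 + 1e-12) {
    warn("plateau I0 + Ia exceeds 1: unphysical overshoot for normalized data.")
  }
  dt <- frame_interval_s
  t_pre <- -rev(seq_len(n_prebleach)) * dt
  t_post <- seq(dt, duration_s, by = dt)
  times <- c(t_pre, 0, t_post)
  phase <- c(rep("pre", n_prebleach), "bleach", rep("post", length(t_post)))
  # recovery clock starts at the first post-bleach frame
  model <- c(rep(1, n_prebleach), i0, i0 + ia * (1 - exp(-(t_post - dt) / tau_s)))
  bleach <- exp(-bleach_rate_per_s * (times - times[1]))
  seeds <- derive_seeds(seed, n_curves)
  curves <- purrr::map_dfr(seq_len(n_curves), function(j) {
    with_seed(seeds[j], {
      scale <- runif(1, 80, 120)
      roi <- scale * (model * bleach + rnorm(length(times), 0, noise_sd))
      ref <- scale * (bleach + rnorm(length(times), 0, noise_sd))
      tibble(curve_id = j, time_s = times, phase = phase, roi = roi,
             reference = ref, scale = scale)
    })
  })
  truth <- dplyr::distinct(curves[, c("curve_id", "scale")])
  truth$i0 <- i0; truth$ia <- ia; truth$tau_s <- tau_s; truth$mf <- mf
  structure(list(curves = curves[, c("curve_id", "time_s", "phase", "roi",
                                     "reference")],
                 truth = truth[, c("curve_id", "i0", "ia", "tau_s", "mf",
                                   "scale")]),
            class = "frap_sim")
}
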
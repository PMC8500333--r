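#' Configuration for the synthetic spindle simulator
#'
#' Bundles every parameter of the forward model used to simulate a two-channel
#' (midzone crosslinker + DNA) time-lapse of an elongating bipolar spindle.
#' Defaults encode the phenomenology measured in gene-edited RPE1 cells: poles
#' ~8 um apart in metaphase elongating to a ~20 um plateau over the first
#' ~5 min of anaphase, a crosslinker axial profile evolving from one Gaussian
#' into a central peak flanked by two identical equidistant side peaks whose
#' central FWHM decays mono-exponentially towards 1.7 um while the central
#' amplitude rises, and a DNA profile of two separating identical Gaussians.
#'
#' The axial profile conserves its integrated intensity: a `central_frac_*`
#' schedule moves mass from the side peaks into the central peak, so the
#' central amplitude rises as the overlap compacts without creating or
#' destroying signal (photobleaching, when enabled, is the only sink).
#'
#' @param duration_min Total simulated time (minutes).
#' @param frame_interval_s Time between frames (seconds).
#' @param pixel_size_um Pixel size (um/pixel).
#' @param image_shape Integer `c(Y, X)` image size in pixels.
#' @param pole_distance_metaphase_um,pole_distance_plateau_um Pole-to-pole
#'   distance in metaphase and at the anaphase plateau (um).
#' @param elongation_duration_min Time over which the spindle elongates
#'   linearly from the metaphase to the plateau length (minutes).
#' @param anaphase_onset_min Time of anaphase onset (minutes from movie start).
#' @param overlap_fwhm_initial_um,overlap_fwhm_final_um,overlap_decay_tau_min
#'   Mono-exponential schedule of the central-peak FWHM after onset (um, um,
#'   minutes).
#' @param central_frac_initial,central_frac_final,central_frac_tau_min
#'   Mono-exponential schedule of the fraction of axial intensity in the
#'   central peak after onset (the central-amplitude schedule).
#' @param side_sigma_um Side-peak Gaussian sigma (um), constant in time.
#' @param total_intensity Integrated axial intensity of the crosslinker
#'   profile; `NULL` scales it so the metaphase peak amplitude is 1.
#' @param dna_amp,dna_sigma_um DNA Gaussian amplitude and sigma (um).
#' @param dna_slow_rate_um_per_min Chromosome separation rate after the
#'   spindle-length plateau (um/min); during elongation the chromosomes
#'   separate at the pole elongation rate.
#' @param transverse_sigma_um,dna_transverse_sigma_um Transverse Gaussian
#'   envelope sigmas used when rendering 2D frames (um).
#' @param background Constant background intensity added to rendered images.
#' @param bleach_rate_per_s Global mono-exponential photobleaching rate (1/s).
#' @param noise_model `"none"`, `"gaussian"` (additive, `noise_sd`), or
#'   `"poisson"` (scaled Poisson with `poisson_gain` counts per intensity
#'   unit).
#' @param noise_sd Gaussian noise SD, in units of the metaphase peak
#'   amplitude.
#' @param poisson_gain Counts per intensity unit for the Poisson model.
#' @param rotation_deg,offset_px In-plane rotation of the spindle axis and
#'   `c(x, y)` offset of the spindle midpoint from the image centre (pixels);
#'   nonzero values exercise the alignment stage.
#' @param seed Master seed; fully determines the output.
#' @return A validated `spindle_sim_config` object (a named list).
#' @export
spindle_sim_config <- function(duration_min = 15,
                               frame_interval_s = 30,
                               pixel_size_um = 0.1,
                               image_shape = c(140L, 320L),
                               pole_distance_metaphase_um = 8,
                               pole_distance_plateau_um = 20,
                               elongation_duration_min = 5,
                               anaphase_onset_min = 5,
                               overlap_fwhm_initial_um = 6,
                               overlap_fwhm_final_um = 1.7,
                               overlap_decay_tau_min = 2,
                               central_frac_initial = 0.4,
                               central_frac_final = 0.85,
                               central_frac_tau_min = 3,
                               side_sigma_um = 0.9,
                               total_intensity = NULL,
                               dna_amp = 1,
                               dna_sigma_um = 1.5,
                               dna_slow_rate_um_per_min = 0.3,
                               transverse_sigma_um = 2,
                               dna_transverse_sigma_um = 2.5,
                               background = 0,
                               bleach_rate_per_s = 0,
                               noise_model = c("none", "gaussian", "poisson"),
                               noise_sd = 0.02,
                               poisson_gain = 200,
                               rotation_deg = 0,
                               offset_px = c(0, 0),
                               seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- as.list(environment())
  if (!(cfg$pole_distance_plateau_um > cfg$pole_distance_metaphase_um &&
        cfg$pole_distance_metaphase_um > 0)) {
    abort("need pole_distance_plateau_um > pole_distance_metaphase_um > 0.")
  }
  if (!(cfg$overlap_fwhm_final_um < cfg$overlap_fwhm_initial_um)) {
    abort("need overlap_fwhm_final_um < overlap_fwhm_initial_um.")
  }
  pos <- c("frame_interval_s", "pixel_size_um", "overlap_fwhm_final_um",
           "overlap_decay_tau_min", "side_sigma_um", "dna_sigma_um",
           "transverse_sigma_um", "dna_transverse_sigma_um", "dna_amp",
           "central_frac_tau_min", "poisson_gain")
  for (p in pos) if (cfg[[p]] <= 0) abort(sprintf("`%s` must be > 0.", p))
  if (cfg$central_frac_initial <= 0 || cfg$central_frac_final >= 1) {
    abort("central fractions must lie in (0, 1).")
  }
  span_x <- image_shape[2] * pixel_size_um
  if (span_x < pole_distance_plateau_um + 6 * side_sigma_um) {
    abort(sprintf(paste0(
      "image too small to contain the plateau spindle: axial span %.1f um < ",
      "plateau length %.1f um + side-peak margin %.1f um."),
      span_x, pole_distance_plateau_um, 6 * side_sigma_um))
  }
  if (is.null(cfg$total_intensity)) {
    sigma_m <- fwhm_to_sigma(pole_distance_metaphase_um)
    cfg$total_intensity <- sigma_m * sqrt(2 * pi)  # metaphase peak amp = 1
  }
  structure(cfg, class = "spindle_sim_config")
}

#' Ground-truth schedules of the spindle simulator
#'
#' Evaluates every time-dependent model parameter of a [spindle_sim_config()]
#' on the frame grid: pole positions, the axial profile model parameters of
#' both channels, and the photobleaching factor. This is the ground truth that
#' downstream fits are compared against.
#'
#' @param config A `spindle_sim_config`.
#' @return A tibble with one row per frame (0-based `frame`).
#' @export
spindle_truth <- function(config) {
  stopifnot(inherits(config, "spindle_sim_config"))
  cfg <- config
  t_s <- seq(0, cfg$duration_min * 60, by = cfg$frame_interval_s)
  t_min <- t_s / 60
  t_on <- cfg$anaphase_onset_min
  dt <- pmax(0, t_min - t_on)                      # minutes since onset
  ramp <- pmin(1, dt / cfg$elongation_duration_min)
  D_m <- cfg$pole_distance_metaphase_um
  D_p <- cfg$pole_distance_plateau_um
  D <- D_m + (D_p - D_m) * ramp
  anaphase <- t_min >= t_on

  # central-peak FWHM and central mass fraction, mono-exponential after onset
  L <- cfg$overlap_fwhm_final_um +
    (cfg$overlap_fwhm_initial_um - cfg$overlap_fwhm_final_um) *
    exp(-dt / cfg$overlap_decay_tau_min)
  f <- cfg$central_frac_final +
    (cfg$central_frac_initial - cfg$central_frac_final) *
    exp(-dt / cfg$central_frac_tau_min)

  M <- cfg$total_intensity
  s2p <- sqrt(2 * pi)
  sigma_m <- fwhm_to_sigma(D_m)
  sigma_c <- fwhm_to_sigma(L)
  sigma_s <- cfg$side_sigma_um
  d <- (D - sigma_to_fwhm(sigma_s)) / 2            # so W = 2d + side FWHM = D
  amp_c <- f * M / (sigma_c * s2p)
  amp_s <- (1 - f) * M / (2 * sigma_s * s2p)

  # chromosome separation: tracks pole elongation, then a slow residual rate
  elong_end <- t_on + cfg$elongation_duration_min
  sep <- ifelse(anaphase,
                (D - D_m) + cfg$dna_slow_rate_um_per_min * pmax(0, t_min - elong_end),
                0)

  tibble(
    frame = seq_along(t_s) - 1L,
    time_s = t_s,
    time_min = t_min,
    time_from_onset_min = t_min - t_on,
    phase = ifelse(anaphase, "anaphase", "metaphase"),
    pole_distance_um = D,
    pole1_x_um = -D / 2,
    pole2_x_um = D / 2,
    model = ifelse(anaphase, "anaphase", "metaphase"),
    amp = ifelse(anaphase, NA_real_, M / (sigma_m * s2p)),
    sigma = ifelse(anaphase, NA_real_, sigma_m),
    amp_c = ifelse(anaphase, amp_c, NA_real_),
    sigma_c = ifelse(anaphase, sigma_c, NA_real_),
    amp_s = ifelse(anaphase, amp_s, NA_real_),
    d = ifelse(anaphase, d, NA_real_),
    sigma_s = ifelse(anaphase, sigma_s, NA_real_),
    central_fwhm_um = ifelse(anaphase, L, NA_real_),
    total_width_um = ifelse(anaphase, D, NA_real_),
    dna_amp = cfg$dna_amp,
    dna_sigma_um = cfg$dna_sigma_um,
    dna_separation_um = sep,
    bleach_factor = exp(-cfg$bleach_rate_per_s * t_s)
  )
}

# profile_model for one truth row, given channel
truth_row_model <- function(row, channel = c("prc1", "dna")) {
  channel <- match.arg(channel)
  if (channel == "dna") {
    dna_model(amp = row$dna_amp, midpoint = 0, separation = row$dna_separation_um,
              sigma = row$dna_sigma_um)
  } else if (row$model == "metaphase") {
    metaphase_model(amp = row$amp, x0 = 0, sigma = row$sigma)
  } else {
    anaphase_model(amp_c = row$amp_c, x0 = 0, sigma_c = row$sigma_c,
                   amp_s = row$amp_s, d = row$d, sigma_s = row$sigma_s)
  }
}

# Mean of the transverse Gaussian envelope over a band of height `width_um`
transverse_band_factor <- function(sigma_t, width_um) {
  h <- width_um / 2
  sigma_t * sqrt(2 * pi) * (2 * stats::pnorm(h / sigma_t) - 1) / width_um
}

apply_noise <- function(x, cfg, seed) {
  switch(cfg$noise_model,
    none = x,
    gaussian = x + with_seed(seed, rnorm(length(x), 0, cfg$noise_sd)),
    poisson = with_seed(seed, rpois(length(x), pmax(x, 0) * cfg$poisson_gain)) /
      cfg$poisson_gain
  )
}

#' Simulate a two-channel spindle movie with ground truth
#'
#' Renders each frame of the forward model onto the pixel grid: the axial
#' profile of the scheduled model multiplied by a transverse Gaussian
#' envelope, rotated/offset as configured, times the photobleaching factor,
#' plus background and noise. Channel 1 is the midzone crosslinker, channel 2
#' the DNA.
#'
#' @param config A [spindle_sim_config()].
#' @return A list of class `spindle_movie_sim` with elements `stack` (an
#'   [image_stack()]), `poles` (per-frame pole pixel coordinates, the manual
#'   centrosome annotations a real analysis would consume), `truth` (the
#'   [spindle_truth()] tibble) and `config`.
#' @export
generate_spindle_movie <- function(config) {
  stopifnot(inherits(config, "spindle_sim_config"))
  cfg <- config
  truth <- spindle_truth(cfg)
  ny <- cfg$image_shape[1]; nx <- cfg$image_shape[2]
  p <- cfg$pixel_size_um
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- cfg$rotation_deg * pi / 180
  ox <- cfg$offset_px[1] * p; oy <- cfg$offset_px[2] * p

  # pixel-centre coordinates relative to spindle midpoint, in um
  px <- (seq_len(nx) - cx) * p - ox
  py <- (seq_len(ny) - cy) * p - oy
  X <- matrix(px, ny, nx, byrow = TRUE)
  Y <- matrix(py, ny, nx)
  U <- cos(th) * X + sin(th) * Y      # along spindle axis
  V <- -sin(th) * X + cos(th) * Y     # transverse

  nt <- nrow(truth)
  data <- array(0, dim = c(nt, 2L, ny, nx))
  seeds <- derive_seeds(cfg$seed, 2L * nt)
  env_p <- exp(-V^2 / (2 * cfg$transverse_sigma_um^2))
  env_d <- exp(-V^2 / (2 * cfg$dna_transverse_sigma_um^2))
  for (i in seq_len(nt)) {
    row <- truth[i, ]
    bf <- row$bleach_factor
    prc1 <- profile_eval(truth_row_model(row, "prc1"), U) * env_p * bf +
      cfg$background
    dna <- profile_eval(truth_row_model(row, "dna"), U) * env_d * bf +
      cfg$background
    data[i, 1L, , ] <- apply_noise(prc1, cfg, seeds[2 * i - 1])
    data[i, 2L, , ] <- apply_noise(dna, cfg, seeds[2 * i])
  }

  # forward-map pole coordinates (u = +-D/2, v = 0) to pixel space
  poles <- dplyr::mutate(
    truth[, c("frame", "pole1_x_um", "pole2_x_um")],
    x1 = cx + (cos(th) * .data$pole1_x_um + ox) / p,
    y1 = cy + (sin(th) * .data$pole1_x_um + oy) / p,
    x2 = cx + (cos(th) * .data$pole2_x_um + ox) / p,
    y2 = cy + (sin(th) * .data$pole2_x_um + oy) / p
  )[, c("frame", "x1", "y1", "x2", "y2")]

  structure(
    list(
      stack = image_stack(data, pixel_size_um = p,
                          frame_interval_s = cfg$frame_interval_s,
                          channel_names = c("prc1", "dna")),
      poles = poles, truth = truth, config = cfg
    ),
    class = "spindle_movie_sim"
  )
}

#' Simulate a spindle kymograph directly from the profile schedules
#'
#' Shortcut that skips 2D rendering and band extraction: each kymograph row is
#' the scheduled axial profile (scaled by the analytic transverse band factor,
#' so it matches what [extract_kymograph()] measures on a rendered movie),
#' times the bleaching factor, plus background and per-pixel noise.
#'
#' @param config A [spindle_sim_config()].
#' @param line_width_um Band width represented by the analytic transverse
#'   factor (um).
#' @return A list of class `spindle_kymo_sim`: `kymo` (a [kymograph()]) and
#'   `truth` / `config` as in [generate_spindle_movie()]. The kymograph
#'   carries the true onset frame and metaphase pole distance.
#' @export
generate_spindle_kymograph <- function(config, line_width_um = 8) {
  stopifnot(inherits(config, "spindle_sim_config"))
  cfg <- config
  truth <- spindle_truth(cfg)
  nx <- cfg$image_shape[2]
  x <- (seq_len(nx) - (nx + 1) / 2) * cfg$pixel_size_um
  fp <- transverse_band_factor(cfg$transverse_sigma_um, line_width_um)
  fd <- transverse_band_factor(cfg$dna_transverse_sigma_um, line_width_um)
  nt <- nrow(truth)
  seeds <- derive_seeds(cfg$seed, 2L * nt)
  prc1 <- dna <- matrix(0, nt, nx)
  for (i in seq_len(nt)) {
    row <- truth[i, ]
    bf <- row$bleach_factor
    prc1[i, ] <- apply_noise(
      profile_eval(truth_row_model(row, "prc1"), x) * fp * bf + cfg$background,
      cfg, seeds[2 * i - 1])
    dna[i, ] <- apply_noise(
      profile_eval(truth_row_model(row, "dna"), x) * fd * bf + cfg$background,
      cfg, seeds[2 * i])
  }
  ana <- truth$frame[truth$phase == "anaphase"]
  onset <- if (length(ana) == 0) NA_integer_ else min(ana)
  ky <- kymograph(list(prc1 = prc1, dna = dna), x_um = x,
                  frame_interval_s = cfg$frame_interval_s,
                  pixel_size_um = cfg$pixel_size_um,
                  onset_frame = onset,
                  metaphase_pole_distance_um = cfg$pole_distance_metaphase_um)
  structure(list(kymo = ky, truth = truth, config = cfg),
            class = "spindle_kymo_sim")
}
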
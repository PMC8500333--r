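#' Axial intensity profile models
#'
#' Constructors for the three profile models used throughout the pipeline:
#'
#' * `metaphase_model()` — a single Gaussian plus constant baseline. Its FWHM
#'   is the metaphase spindle length as labelled by the midzone crosslinker.
#' * `anaphase_model()` — one central Gaussian flanked by two side Gaussians
#'   constrained to be equidistant from the centre and identical in height and
#'   width, plus baseline. The central FWHM `L = 2.3548 * sigma_c` is the
#'   antiparallel overlap length; the total width is
#'   `W = 2 * d + 2.3548 * sigma_s` (side-peak separation plus one side FWHM).
#' * `dna_model()` — two spatially displaced, otherwise identical Gaussians
#'   plus baseline; `separation` is the distance between the chromosome masses.
#'
#' @param amp,amp_c,amp_s Peak amplitudes (intensity units, >= 0).
#' @param x0,midpoint Peak centre / profile midpoint (um).
#' @param sigma,sigma_c,sigma_s Gaussian standard deviations (um, > 0).
#' @param d Distance from the centre to each side-peak centre (um, > 0).
#' @param separation Distance between the two DNA Gaussian means (um, >= 0).
#' @param baseline Constant baseline intensity.
#' @return An object of class `profile_model`; calling `profile_eval(model, x)`
#'   evaluates it on an axial grid.
#' @examples
#' m <- anaphase_model(amp_c = 5, x0 = 0, sigma_c = fwhm_to_sigma(1.7),
#'                     amp_s = 1, d = 8.94, sigma_s = 0.9)
#' profile_eval(m, seq(-12, 12, by = 0.1))[1:3]
#' @export
metaphase_model <- function(amp = 1, x0 = 0, sigma = 1, baseline = 0) {
  stopifnot(amp >= 0, sigma > 0)
  structure(list(kind = "metaphase", amp = amp, x0 = x0, sigma = sigma,
                 baseline = baseline),
            class = "profile_model")
}

#' @rdname metaphase_model
#' @export
anaphase_model <- function(amp_c = 1, x0 = 0, sigma_c = 1, amp_s = 0.3, d = 5,
                           sigma_s = 1, baseline = 0) {
  stopifnot(amp_c >= 0, amp_s >= 0, sigma_c > 0, sigma_s > 0, d > 0)
  structure(list(kind = "anaphase", amp_c = amp_c, x0 = x0, sigma_c = sigma_c,
                 amp_s = amp_s, d = d, sigma_s = sigma_s, baseline = baseline),
            class = "profile_model")
}

#' @rdname metaphase_model
#' @export
dna_model <- function(amp = 1, midpoint = 0, separation = 0, sigma = 1,
                      baseline = 0) {
  stopifnot(amp >= 0, sigma > 0, separation >= 0)
  structure(list(kind = "dna", amp = amp, midpoint = midpoint,
                 separation = separation, sigma = sigma, baseline = baseline),
            class = "profile_model")
}

gauss <- function(x, amp, x0, sigma) amp * exp(-((x - x0)^2) / (2 * sigma^2))

#' Evaluate a profile model on an axial grid
#'
#' @param model A `profile_model` from [metaphase_model()], [anaphase_model()]
#'   or [dna_model()].
#' @param x Axial positions (um).
#' @return Numeric vector of intensities, `length(x)`.
#' @export
profile_eval <- function(model, x) {
  stopifnot(inherits(model, "profile_model"))
  with(model, switch(kind,
    metaphase = gauss(x, amp, x0, sigma) + baseline,
    anaphase = gauss(x, amp_c, x0, sigma_c) +
      gauss(x, amp_s, x0 - d, sigma_s) +
      gauss(x, amp_s, x0 + d, sigma_s) + baseline,
    dna = gauss(x, amp, midpoint - separation / 2, sigma) +
      gauss(x, amp, midpoint + separation / 2, sigma) + baseline
  ))
}

#' @export
print.profile_model <- function(x, ...) {
  cat("<profile_model:", x$kind, ">\n")
  pars <- x[setdiff(names(x), "kind")]
  cat(paste0("  ", names(pars), " = ", vapply(pars, format, ""), collapse = "\n"), "\n")
  invisible(x)
}

# Analytic integral over the axial axis (baseline excluded)
profile_mass <- function(model) {
  s2p <- sqrt(2 * pi)
  with(model, switch(kind,
    metaphase = amp * sigma * s2p,
    anaphase = amp_c * sigma_c * s2p + 2 * amp_s * sigma_s * s2p,
    dna = 2 * amp * sigma * s2p
  ))
}

#' Sample a profile model on a grid, optionally with noise
#'
#' Unit-test and simulation fixture: evaluates a profile model on a strictly
#' increasing axial grid and adds i.i.d. Gaussian noise. With `noise_sd = 0`
#' the returned intensities equal the model exactly.
#'
#' @param model A `profile_model`.
#' @param x_grid Strictly increasing axial positions (um).
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param seed Optional integer seed; when given the output is reproducible
#'   and the global RNG state is untouched.
#' @return A tibble with columns `x_um`, `intensity`.
#' @export
generate_profile <- function(model, x_grid, noise_sd = 0, seed = NULL) {
  if (any(diff(x_grid) <= 0)) abort("`x_grid` must be strictly increasing.")
  y <- profile_eval(model, x_grid)
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) rnorm(length(y), 0, noise_sd)
           else with_seed(seed, rnorm(length(y), 0, noise_sd))
    y <- y + eps
  }
  tibble(x_um = as.numeric(x_grid), intensity = y)
}
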
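# light smoothing used only to seed initial parameter guesses
running_mean <- function(y, k = 5) {
  n <- length(y)
  if (n < k) return(y)
  stats::filter(y, rep(1 / k, k), sides = 2) |>
    as.numeric() |>
    (\(s) ifelse(is.na(s), y, s))()
}

# deriv()-generated model evaluators (value + analytic gradient)
eval_gauss <- deriv(
  ~ amp * exp(-(x - x0)^2 / (2 * sigma^2)) + baseline,
  c("amp", "x0", "sigma", "baseline"),
  function.arg = c("amp", "x0", "sigma", "baseline", "x"))

eval_anaphase <- deriv(
  ~ amp_c * exp(-(x - x0)^2 / (2 * sigma_c^2)) +
    amp_s * exp(-(x - x0 + d)^2 / (2 * sigma_s^2)) +
    amp_s * exp(-(x - x0 - d)^2 / (2 * sigma_s^2)) + baseline,
  c("amp_c", "x0", "sigma_c", "amp_s", "d", "sigma_s", "baseline"),
  function.arg = c("amp_c", "x0", "sigma_c", "amp_s", "d", "sigma_s",
                   "baseline", "x"))

eval_dna <- deriv(
  ~ amp * (exp(-(x - midpoint + separation / 2)^2 / (2 * sigma^2)) +
             exp(-(x - midpoint - separation / 2)^2 / (2 * sigma^2))) +
    baseline,
  c("amp", "midpoint", "separation", "sigma", "baseline"),
  function.arg = c("amp", "midpoint", "separation", "sigma", "baseline", "x"))

profile_weights <- function(profile) {
  if ("sem" %in% names(profile) && all(is.finite(profile$sem)) &&
      all(profile$sem > 0)) {
    1 / profile$sem^2
  } else {
    NULL
  }
}

new_profile_fit <- function(subclass, pars, se, extra = list(), data = NULL) {
  structure(c(list(coefficients = pars, se = se, data = data), extra),
            class = c(subclass, "profile_fit"))
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Fit a single Gaussian to a metaphase axial profile
#'
#' Weighted least-squares fit of `A * exp(-(x - x0)^2 / (2 sigma^2)) + b`.
#' The fitted FWHM (`2 sqrt(2 ln 2) sigma`) is the metaphase spindle length
#' as labelled by the midzone crosslinker. Weights are inverse-variance when
#' the profile carries a `sem` column, else unweighted.
#'
#' @param profile Data frame with columns `x_um`, `intensity` (optional
#'   `sem`), at least 6 points.
#' @return A `metaphase_fit` object: coefficients `amp`, `x0`, `sigma`,
#'   `baseline`, standard errors, `fwhm_um` (+ SE), `converged`.
#' @export
fit_metaphase_profile <- function(profile) {
  profile <- assert_profile(profile, min_points = 6)
  x <- profile$x_um; y <- profile$intensity
  step <- min(diff(x)); span <- diff(range(x))
  b0 <- min(y); A0 <- max(y) - b0
  w0 <- pmax(y - b0, 0)
  x00 <- if (sum(w0) > 0) sum(x * w0) / sum(w0) else mean(x)
  s0 <- sqrt(max(sum(w0 * (x - x00)^2) / max(sum(w0), 1e-12), step^2))
  fit <- try_ls(
    eval_gauss,
    start = c(amp = A0, x0 = x00, sigma = s0, baseline = b0),
    lower = c(amp = 0, x0 = min(x), sigma = step / 2, baseline = -Inf),
    upper = c(amp = Inf, x0 = max(x), sigma = span, baseline = Inf),
    x = x, y = y, weights = profile_weights(profile)
  )
  if (is.null(fit)) {
    pars <- c(amp = A0, x0 = x00, sigma = s0, baseline = b0)
    return(new_profile_fit("metaphase_fit", pars,
                           setNames(rep(NA_real_, 4), names(pars)),
                           list(fwhm_um = sigma_to_fwhm(s0),
                                fwhm_se = NA_real_, converged = FALSE,
                                fit = NULL), data = profile))
  }
  pars <- fit$par; se <- fit$se
  new_profile_fit("metaphase_fit", pars, se,
                  list(fwhm_um = sigma_to_fwhm(pars[["sigma"]]),
                       fwhm_se = sigma_to_fwhm(1) * se[["sigma"]],
                       converged = TRUE, fit = fit), data = profile)
}

anaphase_inits <- function(x, y, step, span) {
  ys <- running_mean(y, 5)
  b0 <- min(y)
  i_max <- which.max(ys)
  x0c <- x[i_max]
  # second moment of the central third seeds sigma_c
  central <- abs(x - x0c) <= span / 6
  wc <- pmax(ys[central] - b0, 0)
  sc0 <- sqrt(max(sum(wc * (x[central] - x0c)^2) / max(sum(wc), 1e-12),
                  step^2))
  sc0 <- min(sc0, span / 6)
  # outer local maxima (after light smoothing) seed the side-peak offset;
  # strict local maxima so the decaying central tail is never mistaken for a
  # side peak
  local_max <- function(idx) {
    idx <- idx[idx > 1 & idx < length(ys)]
    lm_ <- idx[ys[idx] > ys[idx - 1] & ys[idx] >= ys[idx + 1]]
    if (length(lm_) == 0) NA_integer_ else lm_[which.max(ys[lm_])]
  }
  left <- which(x < x0c - 2 * sc0); right <- which(x > x0c + 2 * sc0)
  d0 <- span / 4
  a_s0 <- max(ys) / 4
  il <- local_max(left); ir <- local_max(right)
  if (!is.na(il) && !is.na(ir)) {
    d0 <- (x[ir] - x[il]) / 2
    a_s0 <- max((ys[il] + ys[ir]) / 2 - b0, max(ys) / 20)
  }
  list(amp_c = max(y) - b0, x0 = x0c, sigma_c = sc0,
       amp_s = a_s0, d = max(d0, 2 * step), sigma_s = max(sc0, 2 * step),
       baseline = b0)
}

#' Fit the constrained anaphase profile model
#'
#' Least-squares fit of one central Gaussian plus two side Gaussians
#' constrained to identical height and width and equidistant from the centre
#' (7 free parameters), plus a constant baseline. Reports the antiparallel
#' overlap length `L` (central-peak FWHM) and the total profile width
#' `W = 2 d + FWHM(side)`. Initial values come from the profile centroid, the
#' second moment of its central third and the outer local maxima after light
#' smoothing; on failure the fit is retried from 5 seeded perturbations of
#' these guesses. A degenerate result (vanishing side peaks or a central peak
#' wider than the side-peak offset) falls back to the single-Gaussian model
#' with `L` marked unreliable.
#'
#' The reliability flag for `L` requires a relative SE of `sigma_c` below
#' 50%, `sigma_c < d`, and a central peak taller than the side peaks.
#'
#' @param profile Data frame with `x_um`, `intensity` (optional `sem`), at
#'   least 10 points spanning both shoulders.
#' @return An `anaphase_fit`: coefficients `amp_c`, `x0`, `sigma_c`, `amp_s`,
#'   `d`, `sigma_s`, `baseline` with SEs; `central_fwhm_um` (`L`),
#'   `total_width_um` (`W`) with SEs; flags `reliable`, `fallback`,
#'   `converged`.
#' @export
fit_anaphase_profile <- function(profile) {
  profile <- assert_profile(profile, min_points = 10)
  x <- profile$x_um; y <- profile$intensity
  step <- min(diff(x)); span <- diff(range(x))
  init <- anaphase_inits(x, y, step, span)
  lower <- c(amp_c = 0, x0 = min(x), sigma_c = step / 2, amp_s = 0,
             d = step, sigma_s = step / 2, baseline = -Inf)
  upper <- c(amp_c = Inf, x0 = max(x), sigma_c = span, amp_s = Inf,
             d = span / 2, sigma_s = span, baseline = Inf)
  w <- profile_weights(profile)

  fit <- try_ls(eval_anaphase, start = unlist(init), lower = lower,
                upper = upper, x = x, y = y, weights = w)
  # multi-start fallback: 5 seeded perturbations of the initial guesses,
  # also triggered when the first solution leaves residuals well above the
  # profile scale (a local minimum), keeping the lowest-deviance candidate
  poor <- function(f) {
    is.null(f) || !f$converged ||
      sqrt(f$deviance / length(y)) > 0.02 * diff(range(y))
  }
  if (poor(fit)) {
    cands <- list(fit)
    for (s in seq_len(5)) {
      jit <- with_seed(s, {
        j <- lapply(init, function(v) v * exp(rnorm(1, 0, 0.3)))
        j$x0 <- init$x0 + rnorm(1, 0, span / 20)
        j$baseline <- init$baseline
        j$d <- runif(1, 2 * init$sigma_c, span / 2)  # sweep side-peak offset
        j
      })
      jit <- purrr::map2_dbl(names(init), jit[names(init)],
                             ~ min(max(.y, lower[[.x]] + 1e-9), upper[[.x]]))
      names(jit) <- names(init)
      cands <- c(cands, list(try_ls(eval_anaphase, start = jit, lower = lower,
                                    upper = upper, x = x, y = y, weights = w)))
    }
    cands <- purrr::compact(cands)
    if (length(cands) > 0) {
      fit <- cands[[which.min(vapply(cands, `[[`, 1, "deviance"))]]
    }
  }

  degenerate <- FALSE
  if (!is.null(fit)) {
    pars <- fit$par
    degenerate <- pars[["amp_s"]] < 1e-3 * max(pars[["amp_c"]], 1e-12) ||
      pars[["sigma_c"]] >= pars[["d"]]
  }
  if (is.null(fit) || degenerate) {
    mono <- fit_metaphase_profile(profile)
    pars <- c(amp_c = unname(mono$coefficients[["amp"]]),
              x0 = unname(mono$coefficients[["x0"]]),
              sigma_c = unname(mono$coefficients[["sigma"]]),
              amp_s = 0, d = NA_real_, sigma_s = NA_real_,
              baseline = unname(mono$coefficients[["baseline"]]))
    se <- setNames(rep(NA_real_, 7), names(pars))
    se[c("amp_c", "x0", "sigma_c", "baseline")] <-
      mono$se[c("amp", "x0", "sigma", "baseline")]
    return(new_profile_fit("anaphase_fit", pars, se, list(
      central_fwhm_um = sigma_to_fwhm(pars[["sigma_c"]]),
      central_fwhm_se = sigma_to_fwhm(1) * se[["sigma_c"]],
      total_width_um = mono$fwhm_um, total_width_se = mono$fwhm_se,
      reliable = FALSE, fallback = TRUE, converged = mono$converged,
      fit = mono$fit), data = profile))
  }

  pars <- fit$par; se <- fit$se
  K <- sigma_to_fwhm(1)
  W <- 2 * pars[["d"]] + K * pars[["sigma_s"]]
  V <- fit$vcov
  W_se <- if (all(is.finite(V))) {
    sqrt(max(4 * V["d", "d"] + K^2 * V["sigma_s", "sigma_s"] +
               4 * K * V["d", "sigma_s"], 0))
  } else NA_real_
  rel_se_sc <- se[["sigma_c"]] / pars[["sigma_c"]]
  reliable <- is.finite(rel_se_sc) && rel_se_sc < 0.5 &&
    pars[["sigma_c"]] < pars[["d"]] && pars[["amp_c"]] > pars[["amp_s"]]
  new_profile_fit("anaphase_fit", pars, se, list(
    central_fwhm_um = K * pars[["sigma_c"]],
    central_fwhm_se = K * se[["sigma_c"]],
    total_width_um = W, total_width_se = W_se,
    reliable = reliable, fallback = FALSE, converged = TRUE, fit = fit),
    data = profile)
}

#' Fit two identical displaced Gaussians to a DNA profile
#'
#' Least-squares fit of the sum of two spatially displaced, otherwise
#' identical Gaussians plus baseline, yielding the distance between the
#' separating chromosome masses. When the masses are unresolved
#' (`separation < sigma`) the fit is flagged and the separation SE is floored
#' at `sigma / 2`, reflecting the near-flat likelihood there.
#'
#' @param profile Data frame with `x_um`, `intensity` (optional `sem`), at
#'   least 8 points.
#' @return A `dna_fit`: coefficients `amp`, `midpoint`, `separation`,
#'   `sigma`, `baseline` with SEs; flags `resolved`, `converged`.
#' @export
fit_dna_profile <- function(profile) {
  profile <- assert_profile(profile, min_points = 8)
  x <- profile$x_um; y <- profile$intensity
  step <- min(diff(x)); span <- diff(range(x))
  b0 <- min(y)
  w0 <- pmax(y - b0, 0)
  m0 <- if (sum(w0) > 0) sum(x * w0) / sum(w0) else mean(x)
  lft <- x <= m0; rgt <- x > m0
  cl <- if (sum(w0[lft]) > 0) sum(x[lft] * w0[lft]) / sum(w0[lft]) else m0
  cr <- if (sum(w0[rgt]) > 0) sum(x[rgt] * w0[rgt]) / sum(w0[rgt]) else m0
  s0 <- max(cr - cl, 0)
  var_tot <- sum(w0 * (x - m0)^2) / max(sum(w0), 1e-12)
  sig0 <- sqrt(max(var_tot - s0^2 / 4, step^2))
  lower <- c(amp = 0, midpoint = min(x), separation = 0, sigma = step / 2,
             baseline = -Inf)
  upper <- c(amp = Inf, midpoint = max(x), separation = span, sigma = span,
             baseline = Inf)
  w <- profile_weights(profile)
  start_for <- function(s) {
    sg <- sqrt(max(var_tot - s^2 / 4, step^2))
    c(amp = max(y) - b0, midpoint = m0, separation = s, sigma = sg,
      baseline = b0)
  }
  fit <- try_ls(eval_dna, start = start_for(s0), lower = lower, upper = upper,
                x = x, y = y, weights = w)
  # the s = 0 boundary is a local minimum for marginally resolved masses:
  # when the fit lands there (or fails), sweep separation starts and keep the
  # lowest-deviance solution
  if (is.null(fit) || fit$par[["separation"]] < fit$par[["sigma"]]) {
    cands <- list(fit)
    for (s_try in unique(pmin(c(sig0, 2 * sig0, 3 * sig0, span / 4), span))) {
      cands <- c(cands, list(try_ls(eval_dna, start = start_for(s_try),
                                    lower = lower, upper = upper,
                                    x = x, y = y, weights = w)))
    }
    cands <- purrr::compact(cands)
    if (length(cands) > 0) {
      fit <- cands[[which.min(vapply(cands, `[[`, 1, "deviance"))]]
    }
  }
  if (is.null(fit)) {
    pars <- c(amp = max(y) - b0, midpoint = m0, separation = s0, sigma = sig0,
              baseline = b0)
    return(new_profile_fit("dna_fit", pars,
                           setNames(rep(NA_real_, 5), names(pars)),
                           list(separation = s0, separation_se = NA_real_,
                                resolved = NA, converged = FALSE, fit = NULL),
                           data = profile))
  }
  pars <- fit$par; se <- fit$se
  resolved <- pars[["separation"]] >= pars[["sigma"]]
  sep_se <- se[["separation"]]
  if (!resolved) sep_se <- max(sep_se, pars[["sigma"]] / 2, na.rm = TRUE)
  new_profile_fit("dna_fit", pars, se,
                  list(separation = pars[["separation"]],
                       separation_se = sep_se, resolved = resolved,
                       converged = TRUE, fit = fit), data = profile)
}

#' Maximum peak intensity of a profile
#'
#' The mean of the five samples centred on the profile maximum. At a profile
#' boundary the window is clipped (then fewer than five samples enter the
#' mean and a warning flags the estimate).
#'
#' @param profile Data frame with `x_um`, `intensity`, at least 5 points.
#' @return Single numeric intensity, with attribute `n_window` (samples
#'   used).
#' @export
max_peak_intensity <- function(profile) {
  profile <- assert_profile(profile, min_points = 5)
  y <- profile$intensity
  i <- which.max(y)
  lo <- max(1L, i - 2L); hi <- min(length(y), i + 2L)
  if (hi - lo + 1L < 5L) {
    warn("maximum lies at the profile boundary; intensity window clipped.")
  }
  out <- mean(y[lo:hi])
  attr(out, "n_window") <- hi - lo + 1L
  out
}
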
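eval_decay <- deriv(
  ~ L_inf + (L0 - L_inf) * exp(-x / tau_L),
  c("L0", "L_inf", "tau_L"),
  function.arg = c("L0", "L_inf", "tau_L", "x"))

#' Assemble the mitosis time course from an averaged kymograph
#'
#' For every time point of an averaged kymograph, extracts the
#' background-subtracted axial profiles and runs the stage-appropriate fits:
#' the single-Gaussian metaphase model before anaphase onset and the
#' constrained central + two-side-Gaussian model after it for the crosslinker
#' channel, and the two-Gaussian model for the DNA channel. Per-frame fit
#' failures propagate as `NA` gaps; the series never aborts.
#'
#' @param avg An `avg_kymograph` (see [normalize_and_average()]), or the
#'   `kymograph` of a single cell with its onset frame set.
#' @param channel,dna_channel Names of the crosslinker and DNA channels.
#' @param bleach_correct Divide profiles by the fitted global bleaching
#'   factor (see [extract_profile()]).
#' @return An `overlap_timecourse` tibble, one row per frame: `time_min`
#'   (relative to anaphase onset), `phase`, total profile width `W` and its
#'   SE, central-peak FWHM `L`, its SE and reliability flag, 5-point maximum
#'   peak intensity, and the fitted chromosome separation with SE.
#' @export
build_timecourse <- function(avg, channel = "prc1", dna_channel = "dna",
                             bleach_correct = FALSE) {
  is_avg <- inherits(avg, "avg_kymograph")
  if (!is_avg && !inherits(avg, "kymograph")) {
    abort("`avg` must be an avg_kymograph or kymograph.")
  }
  if (is_avg) {
    rel_frames <- avg$rel_frame
  } else {
    if (is.null(avg$onset_frame)) abort("kymograph has no onset frame defined.")
    nt <- nrow(avg$data[[1]])
    rel_frames <- (seq_len(nt) - 1L) - avg$onset_frame
  }
  dt_min <- avg$frame_interval_s / 60
  rows <- purrr::map(rel_frames, function(rf) {
    frame_arg <- if (is_avg) rf else rf + avg$onset_frame
    out <- list(time_min = rf * dt_min,
                phase = if (rf < 0) "metaphase" else "anaphase",
                total_width_um = NA_real_, total_width_se = NA_real_,
                central_fwhm_um = NA_real_, central_fwhm_se = NA_real_,
                central_reliable = FALSE,
                max_intensity = NA_real_,
                dna_separation_um = NA_real_, dna_separation_se = NA_real_)
    prof <- try(extract_profile(avg, frame_arg, channel = channel,
                                bleach_correct = bleach_correct),
                silent = TRUE)
    if (!inherits(prof, "try-error") && sum(is.finite(prof$intensity)) >= 10) {
      prof <- prof[is.finite(prof$intensity), ]
      if (rf < 0) {
        f <- try(fit_metaphase_profile(prof), silent = TRUE)
        if (!inherits(f, "try-error") && f$converged) {
          out$total_width_um <- f$fwhm_um
          out$total_width_se <- f$fwhm_se
        }
      } else {
        f <- try(fit_anaphase_profile(prof), silent = TRUE)
        if (!inherits(f, "try-error") && f$converged) {
          out$total_width_um <- f$total_width_um
          out$total_width_se <- f$total_width_se
          out$central_fwhm_um <- f$central_fwhm_um
          out$central_fwhm_se <- f$central_fwhm_se
          out$central_reliable <- isTRUE(f$reliable)
        }
      }
      out$max_intensity <- as.numeric(suppressWarnings(max_peak_intensity(prof)))
    }
    dpro <- try(extract_profile(avg, frame_arg, channel = dna_channel,
                                bleach_correct = FALSE),
                silent = TRUE)
    if (!inherits(dpro, "try-error") && sum(is.finite(dpro$intensity)) >= 8) {
      dpro <- dpro[is.finite(dpro$intensity), ]
      fd <- try(fit_dna_profile(dpro), silent = TRUE)
      if (!inherits(fd, "try-error") && isTRUE(fd$converged)) {
        out$dna_separation_um <- fd$separation
        out$dna_separation_se <- fd$separation_se
      }
    }
    tibble::as_tibble(out)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("overlap_timecourse", class(out))
  out
}

#' Mono-exponential decay fit to the central-peak width series
#'
#' Fits `L(t) = L_inf + (L0 - L_inf) * exp(-(t - t_ref) / tau_L)` to the
#' reliable central-peak FWHM values of a time course, where `t_ref` is the
#' first reliable time point. The fit extrapolates the overlap length to
#' early-anaphase times at which the constrained profile fit is not yet
#' reliable.
#'
#' @param timecourse An `overlap_timecourse` (from [build_timecourse()]), or
#'   any data frame with columns `time_min`, `central_fwhm_um` and optionally
#'   `central_reliable`, `central_fwhm_se`.
#' @param use_reliable Keep only rows whose reliability flag passes.
#' @return An `overlap_decay_fit` with coefficients `L0` (um, width at
#'   `t_ref`), `L_inf` (um, asymptote), `tau_L` (min), plus `t_ref` and SEs.
#'   A flat series returns `delta_L = 0` with `tau_L` undefined (`NA`);
#'   [predict()] then returns the constant.
#' @export
fit_overlap_decay <- function(timecourse, use_reliable = TRUE) {
  df <- as_tibble(timecourse)
  if (!all(c("time_min", "central_fwhm_um") %in% names(df))) {
    abort("`timecourse` needs columns `time_min` and `central_fwhm_um`.")
  }
  if (use_reliable && "central_reliable" %in% names(df)) {
    df <- df[df$central_reliable %in% TRUE, ]
  }
  df <- df[is.finite(df$time_min) & is.finite(df$central_fwhm_um), ]
  if (nrow(df) < 4) abort("need at least 4 reliable central-width points.")
  t_ref <- min(df$time_min)
  L <- df$central_fwhm_um
  if (diff(range(L)) < 1e-6 * max(mean(L), 1e-12)) {
    pars <- c(L0 = mean(L), L_inf = mean(L), tau_L = NA_real_)
    return(structure(list(coefficients = pars,
                          se = setNames(rep(NA_real_, 3), names(pars)),
                          t_ref = t_ref, delta_L = 0, flat = TRUE,
                          converged = TRUE, fit = NULL),
                     class = "overlap_decay_fit"))
  }
  span <- diff(range(df$time_min))
  w <- if ("central_fwhm_se" %in% names(df) &&
           all(is.finite(df$central_fwhm_se)) && all(df$central_fwhm_se > 0)) {
    1 / df$central_fwhm_se^2
  } else NULL
  dat <- tibble(t = df$time_min - t_ref, L = L)
  fit <- try_ls(
    eval_decay,
    start = c(L0 = L[which.min(dat$t)], L_inf = min(L),
              tau_L = max(span / 3, 1e-3)),
    lower = c(L0 = 0, L_inf = 0, tau_L = 1e-6),
    upper = c(L0 = Inf, L_inf = Inf, tau_L = 1e6),
    x = dat$t, y = dat$L, weights = w
  )
  if (is.null(fit)) abort("overlap decay fit failed to converge.")
  pars <- fit$par; se <- fit$se
  structure(list(coefficients = pars, se = se, t_ref = t_ref,
                 delta_L = pars[["L0"]] - pars[["L_inf"]], flat = FALSE,
                 converged = TRUE, fit = fit),
            class = "overlap_decay_fit")
}

#' @export
print.overlap_decay_fit <- function(x, ...) {
  cat("<overlap_decay_fit>\n")
  if (x$flat) {
    cat(sprintf("  flat series: L = %.4g um (delta_L = 0, tau undefined)\n",
                x$coefficients[["L0"]]))
  } else {
    cat(sprintf("  L(t) = %.4g + (%.4g - %.4g) exp(-(t - %.3g)/%.4g)  [um, min]\n",
                x$coefficients[["L_inf"]], x$coefficients[["L0"]],
                x$coefficients[["L_inf"]], x$t_ref, x$coefficients[["tau_L"]]))
  }
  invisible(x)
}

#' @describeIn fit_overlap_decay Evaluate the fitted (or constant) decay
#'   curve at times `time_min` (minutes relative to anaphase onset),
#'   including extrapolation before `t_ref`.
#' @param object An `overlap_decay_fit`.
#' @param time_min Times at which to evaluate (minutes).
#' @param ... Ignored.
#' @export
predict.overlap_decay_fit <- function(object, time_min, ...) {
  p <- object$coefficients
  if (object$flat) return(rep(p[["L0"]], length(time_min)))
  p[["L_inf"]] + (p[["L0"]] - p[["L_inf"]]) *
    exp(-(time_min - object$t_ref) / p[["tau_L"]])
}
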
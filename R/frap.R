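eval_recovery <- deriv(
  ~ i0 + ia * (1 - exp(-x / tau_s)),
  c("i0", "ia", "tau_s"),
  function.arg = c("i0", "ia", "tau_s", "x"))

frap_value_col <- function(df) {
  if ("intensity" %in% names(df)) "intensity" else if ("roi" %in% names(df)) {
    "roi"
  } else {
    abort("FRAP record needs an `intensity` or `roi` column.")
  }
}

assert_frap <- function(df) {
  need <- c("time_s", "phase")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    abort("FRAP records need columns `time_s` and `phase` ('pre'/'bleach'/'post').")
  }
  if (!"curve_id" %in% names(df)) df$curve_id <- 1L
  df
}

#' Normalize FRAP records to the pre-bleach intensity
#'
#' Divides every intensity of each curve by the mean of that curve's last
#' four pre-bleach samples, so the pre-bleach level is 1. The operation is
#' idempotent and invariant to rescaling of the raw intensities.
#'
#' @param records Tibble with columns `curve_id` (optional), `time_s`,
#'   `phase`, and `roi` or `intensity`.
#' @return The same tibble with a normalized `intensity` column.
#' @export
normalize_frap <- function(records) {
  records <- assert_frap(records)
  val <- frap_value_col(records)
  records |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_modify(function(d, key) {
      pre <- d[[val]][d$phase == "pre"]
      if (length(pre) < 4) {
        abort("fewer than 4 pre-bleach samples: cannot normalize.")
      }
      ref <- mean(utils::tail(pre, 4))
      d$intensity <- d[[val]] / ref
      d
    }) |>
    dplyr::ungroup()
}

#' Correct FRAP records for acquisition photobleaching
#'
#' Divides each curve pointwise by the intensity of a reference region
#' distant from the bleached spot (itself pre-normalized to its own
#' pre-bleach mean), then renormalizes to the pre-bleach level. Used for the
#' fast-bleaching fluorophores (KIF4A, CLASP1 constructs); the slow-bleaching
#' crosslinker channel does not need it.
#'
#' @param records Tibble as in [normalize_frap()], with a `reference` column
#'   (or supply `reference_series`).
#' @param reference_series Optional numeric vector (one value per sample of
#'   each curve) overriding the `reference` column.
#' @return The corrected, renormalized tibble.
#' @export
bleach_correct <- function(records, reference_series = NULL) {
  records <- assert_frap(records)
  val <- frap_value_col(records)
  records |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_modify(function(d, key) {
      ref <- reference_series %||% d$reference
      if (is.null(ref)) abort("no `reference` column or `reference_series` given.")
      if (length(ref) != nrow(d)) {
        abort("reference series must have one value per sample.")
      }
      if (any(!is.finite(ref)) || any(ref <= 0)) {
        abort("reference intensities must be strictly positive.")
      }
      pre <- ref[d$phase == "pre"]
      ref <- ref / mean(utils::tail(pre, 4))
      d$intensity <- d[[val]] / ref
      d
    }) |>
    dplyr::ungroup() |>
    normalize_frap()
}

#' Average normalized FRAP curves of one stage
#'
#' Pointwise mean, SD and SEM over cells on a shared time grid. Curves
#' sampled on different grids are linearly interpolated onto the grid of the
#' first curve.
#'
#' @param records Normalized records (see [normalize_frap()]) with
#'   `curve_id`.
#' @param stage Optional stage label attached to the result.
#' @return A `stage_average_curve` tibble: `time_s`, `phase`, `intensity`
#'   (mean), `sd`, `sem`, `n`; attribute `n_cells`.
#' @export
average_frap_curves <- function(records, stage = NULL) {
  records <- assert_frap(records)
  if (!"intensity" %in% names(records)) {
    abort("records are not normalized; run normalize_frap() first.")
  }
  ids <- unique(records$curve_id)
  if (length(ids) < 1) abort("no curves to average.")
  ref <- records[records$curve_id == ids[1], c("time_s", "phase")]
  vals <- purrr::map(ids, function(id) {
    d <- records[records$curve_id == id, ]
    if (nrow(d) == nrow(ref) && isTRUE(all.equal(d$time_s, ref$time_s))) {
      d$intensity
    } else {
      approx(d$time_s, d$intensity, xout = ref$time_s, rule = 1)$y
    }
  })
  m <- do.call(cbind, vals)
  out <- tibble(
    time_s = ref$time_s, phase = ref$phase,
    intensity = rowMeans(m, na.rm = TRUE),
    sd = apply(m, 1, function(v) if (sum(is.finite(v)) > 1) sd(v, na.rm = TRUE) else 0,
               simplify = TRUE),
    n = apply(m, 1, function(v) sum(is.finite(v)))
  )
  out$sem <- out$sd / sqrt(pmax(out$n, 1))
  attr(out, "n_cells") <- length(ids)
  attr(out, "stage") <- stage
  class(out) <- c("stage_average_curve", class(out))
  out
}

#' Fit the mono-exponential FRAP recovery model
#'
#' Least-squares fit of `I(t) = I0 + Ia (1 - exp(-t / tau))` to the
#' post-bleach samples of a normalized (optionally averaged) curve, with the
#' recovery clock starting at the first post-bleach frame; the bleach-frame
#' sample supplies the initial guess for `I0` and is excluded from the fit.
#' Derived quantities: plateau `IE = I0 + Ia` and recovery (mobile) fraction
#' `mf = Ia / (1 - I0)`, with delta-method standard errors.
#'
#' Parameter bounds: `tau` in `[frame interval, 10 x observation window]`,
#' `I0` in `[0, 1]`, `Ia` in `[0, 1.5]`. A fitted `tau` beyond half the
#' observation window is flagged `window_limited` and its SE is doubled: with
#' so little of the plateau observed the curvature-based SE is an
#' underestimate.
#'
#' @param curve Normalized single curve or [average_frap_curves()] output:
#'   columns `time_s`, `phase`, `intensity` (optional `sem` for weighting).
#' @return A `frap_fit`: coefficients `i0`, `ia`, `tau_s` with SEs, derived
#'   `ie`, `mf` (+ SEs), flags `window_limited`, `at_bounds`, `converged`.
#' @export
fit_recovery <- function(curve) {
  curve <- assert_frap(curve)
  if (!"intensity" %in% names(curve)) {
    abort("curve is not normalized; run normalize_frap() first.")
  }
  if (length(unique(curve$curve_id)) > 1) {
    abort("fit one curve (or one averaged curve) at a time.")
  }
  post <- curve[curve$phase == "post", ]
  if (nrow(post) < 6) abort("need at least 6 post-bleach samples.")
  post <- post[order(post$time_s), ]
  t0 <- min(post$time_s)
  dt <- min(diff(post$time_s))
  window <- max(post$time_s) - t0
  dat <- tibble(t = post$time_s - t0, y = post$intensity)

  i0_guess <- if (any(curve$phase == "bleach")) {
    mean(curve$intensity[curve$phase == "bleach"])
  } else {
    min(dat$y)
  }
  i0_guess <- min(max(i0_guess, 0), 0.99)
  ie_guess <- mean(utils::tail(dat$y, 4))
  ia_guess <- min(max(ie_guess - i0_guess, 1e-3), 1.5)
  thresh <- i0_guess + 0.63 * ia_guess
  above <- which(dat$y >= thresh)
  tau_guess <- if (length(above) > 0) max(dat$t[above[1]], dt) else window / 3

  w <- if ("sem" %in% names(post) && all(is.finite(post$sem)) &&
           all(post$sem > 0)) 1 / post$sem^2 else NULL
  fit <- try_ls(
    eval_recovery,
    start = c(i0 = i0_guess, ia = ia_guess, tau_s = tau_guess),
    lower = c(i0 = 0, ia = 0, tau_s = dt),
    upper = c(i0 = 1, ia = 1.5, tau_s = 10 * window),
    x = dat$t, y = dat$y, weights = w
  )
  if (is.null(fit)) {
    pars <- c(i0 = i0_guess, ia = ia_guess, tau_s = tau_guess)
    return(structure(list(coefficients = pars,
                          se = setNames(rep(NA_real_, 3), names(pars)),
                          ie = i0_guess + ia_guess,
                          mf = ia_guess / (1 - i0_guess),
                          ie_se = NA_real_, mf_se = NA_real_,
                          window_s = window, window_limited = NA,
                          at_bounds = NA, converged = FALSE, fit = NULL,
                          data = curve),
                     class = "frap_fit"))
  }
  pars <- fit$par; se <- fit$se
  i0 <- pars[["i0"]]; ia <- pars[["ia"]]; tau <- pars[["tau_s"]]
  mf <- ia / (1 - i0)
  V <- fit$vcov
  if (all(is.finite(V))) {
    g_ie <- c(1, 1, 0)                                   # d(IE)/d(i0, ia, tau)
    g_mf <- c(ia / (1 - i0)^2, 1 / (1 - i0), 0)          # d(mf)/d(i0, ia, tau)
    ie_se <- sqrt(max(t(g_ie) %*% V %*% g_ie, 0))
    mf_se <- sqrt(max(t(g_mf) %*% V %*% g_mf, 0))
  } else {
    ie_se <- mf_se <- NA_real_
  }
  window_limited <- tau > window / 2
  at_bounds <- tau <= dt * (1 + 1e-6) || tau >= 10 * window * (1 - 1e-6) ||
    i0 >= 1 - 1e-6 || ia >= 1.5 - 1e-6
  if (window_limited && is.finite(se[["tau_s"]])) {
    se[["tau_s"]] <- 2 * se[["tau_s"]]
  }
  structure(list(coefficients = pars, se = se, ie = i0 + ia, mf = mf,
                 ie_se = as.numeric(ie_se), mf_se = as.numeric(mf_se),
                 window_s = window, window_limited = window_limited,
                 at_bounds = at_bounds, converged = TRUE, fit = fit,
                 data = curve),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit>\n")
  cat(sprintf("  tau = %.3g s (SE %.2g)%s\n", x$coefficients[["tau_s"]],
              x$se[["tau_s"]],
              if (isTRUE(x$window_limited)) "  [window-limited]" else ""))
  cat(sprintf("  I0 = %.3g, Ia = %.3g, IE = %.3g, mf = %.3g (SE %.2g)\n",
              x$coefficients[["i0"]], x$coefficients[["ia"]], x$ie, x$mf,
              x$mf_se))
  invisible(x)
}

#' Rule-based mitotic stage classification
#'
#' Deterministic stage label from a DNA profile fit, a crosslinker profile
#' fit and (optionally) the time since mitosis onset. Rules: chromosome
#' separation below 1 um is metaphase; above it, anaphase is split into
#' early/mid/late at thirds of the elongation span (plateau minus metaphase
#' pole distance); telophase additionally requires a plateaued separation and
#' a compact, dominant central crosslinker peak (central FWHM < 2.5 um and a
#' central/side amplitude ratio above 3). Contradictory evidence (metaphase
#' separation with a compact anaphase-like crosslinker profile, or a wide
#' separation with a purely metaphase-like profile) yields `"unknown"`.
#'
#' @param prc1_fit A `metaphase_fit` or `anaphase_fit` of the crosslinker
#'   profile.
#' @param dna_fit A `dna_fit` of the DNA profile.
#' @param time_since_mitosis_min Optional minutes since mitosis onset
#'   (diagnostic only).
#' @param plateau_pole_distance_um,metaphase_pole_distance_um Spindle lengths
#'   defining the anaphase separation span (um).
#' @param separation_rate_um_per_min Optional current separation rate; below
#'   0.5 um/min counts as plateaued. When absent, separation at >= 90% of the
#'   elongation span counts as plateaued.
#' @return Stage label string, with attribute `diagnostics`.
#' @export
classify_stage <- function(prc1_fit, dna_fit, time_since_mitosis_min = NULL,
                           plateau_pole_distance_um = 20,
                           metaphase_pole_distance_um = 8,
                           separation_rate_um_per_min = NULL) {
  stopifnot(inherits(dna_fit, "dna_fit"), inherits(prc1_fit, "profile_fit"))
  s <- dna_fit$separation
  span <- plateau_pole_distance_um - metaphase_pole_distance_um
  is_ana_fit <- inherits(prc1_fit, "anaphase_fit") && !isTRUE(prc1_fit$fallback)
  compact <- is_ana_fit &&
    prc1_fit$central_fwhm_um < 2.5 &&
    prc1_fit$coefficients[["amp_c"]] > 3 * prc1_fit$coefficients[["amp_s"]]
  plateaued <- if (!is.null(separation_rate_um_per_min)) {
    abs(separation_rate_um_per_min) < 0.5
  } else {
    s >= 0.9 * span
  }
  diag <- list(separation_um = s, compact_central_peak = compact,
               plateaued = plateaued,
               time_since_mitosis_min = time_since_mitosis_min)
  label <- if (s < 1) {
    if (compact) "unknown" else "metaphase"
  } else if (!is_ana_fit && s >= 2 * span / 3) {
    "unknown"  # wide separation but purely metaphase-like crosslinker profile
  } else if (plateaued && compact) {
    "telophase"
  } else if (s < span / 3) {
    "early_anaphase"
  } else if (s < 2 * span / 3) {
    "mid_anaphase"
  } else {
    "late_anaphase"
  }
  structure(label, diagnostics = diag)
}
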
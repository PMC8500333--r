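#' Tidy a fitted profile model
#'
#' @param x A `metaphase_fit`, `anaphase_fit` or `dna_fit`.
#' @param ... Ignored.
#' @return Tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy profile_fit
#' @export
tidy.profile_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se[names(x$coefficients)]))
}

#' @method glance metaphase_fit
#' @export
glance.metaphase_fit <- function(x, ...) {
  tibble(fwhm_um = x$fwhm_um, fwhm_se = x$fwhm_se, converged = x$converged)
}

#' @method glance anaphase_fit
#' @export
glance.anaphase_fit <- function(x, ...) {
  tibble(central_fwhm_um = x$central_fwhm_um,
         central_fwhm_se = x$central_fwhm_se,
         total_width_um = x$total_width_um,
         total_width_se = x$total_width_se,
         reliable = x$reliable, fallback = x$fallback,
         converged = x$converged)
}

#' @method glance dna_fit
#' @export
glance.dna_fit <- function(x, ...) {
  tibble(separation_um = x$separation, separation_se = x$separation_se,
         resolved = x$resolved, converged = x$converged)
}

#' Tidy a FRAP recovery fit
#'
#' @param x A `frap_fit`.
#' @param ... Ignored.
#' @return `tidy()`: `term`/`estimate`/`std.error` for `i0`, `ia`, `tau_s`.
#'   `glance()`: one row with `tau_s`, `mf`, `ie` (+ SEs) and the fit flags.
#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se))
}

#' @rdname tidy.frap_fit
#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(tau_s = x$coefficients[["tau_s"]], tau_se = x$se[["tau_s"]],
         mf = x$mf, mf_se = x$mf_se, ie = x$ie, ie_se = x$ie_se,
         i0 = x$coefficients[["i0"]], ia = x$coefficients[["ia"]],
         window_limited = x$window_limited, at_bounds = x$at_bounds,
         converged = x$converged)
}

#' @method tidy overlap_decay_fit
#' @export
tidy.overlap_decay_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se))
}

#' @method glance overlap_decay_fit
#' @export
glance.overlap_decay_fit <- function(x, ...) {
  tibble(L0_um = x$coefficients[["L0"]], L_inf_um = x$coefficients[["L_inf"]],
         tau_L_min = x$coefficients[["tau_L"]], t_ref_min = x$t_ref,
         delta_L_um = x$delta_L, flat = x$flat, converged = x$converged)
}

#' Reconstruct the fitted profile model from a fit object
#'
#' @param fit A `metaphase_fit`, `anaphase_fit` or `dna_fit`.
#' @return A `profile_model` evaluable with [profile_eval()]. An anaphase
#'   fallback fit (single Gaussian) returns a metaphase model.
#' @export
as_profile_model <- function(fit) {
  stopifnot(inherits(fit, "profile_fit"))
  p <- fit$coefficients
  if (inherits(fit, "metaphase_fit")) {
    metaphase_model(p[["amp"]], p[["x0"]], p[["sigma"]], p[["baseline"]])
  } else if (inherits(fit, "anaphase_fit")) {
    if (isTRUE(fit$fallback)) {
      metaphase_model(p[["amp_c"]], p[["x0"]], p[["sigma_c"]], p[["baseline"]])
    } else {
      anaphase_model(p[["amp_c"]], p[["x0"]], p[["sigma_c"]], p[["amp_s"]],
                     p[["d"]], p[["sigma_s"]], p[["baseline"]])
    }
  } else if (inherits(fit, "dna_fit")) {
    dna_model(p[["amp"]], p[["midpoint"]], p[["separation"]], p[["sigma"]],
              p[["baseline"]])
  } else {
    abort("unknown profile fit class.")
  }
}
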
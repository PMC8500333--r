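#' Plot a profile fit over its data
#'
#' @param object A `metaphase_fit`, `anaphase_fit` or `dna_fit`.
#' @param ... Ignored.
#' @return A ggplot: profile points and the fitted curve.
#' @method autoplot profile_fit
#' @export
autoplot.profile_fit <- function(object, ...) {
  stopifnot(!is.null(object$data))
  xg <- seq(min(object$data$x_um), max(object$data$x_um), length.out = 400)
  curve <- tibble(x_um = xg,
                  intensity = profile_eval(as_profile_model(object), xg))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x_um, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::labs(x = "axial position (µm)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a kymograph or averaged kymograph
#'
#' @param object A `kymograph` or `avg_kymograph`.
#' @param ... Ignored.
#' @return A ggplot raster, time (min) downwards, one facet per channel.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$time_s / 60,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "axial position (µm)", y = "time (min)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kymograph
#' @method autoplot avg_kymograph
#' @export
autoplot.avg_kymograph <- autoplot.kymograph

#' Plot a FRAP fit over its curve
#'
#' @param object A `frap_fit`.
#' @param ... Ignored.
#' @return A ggplot of the normalized recovery and the fitted
#'   mono-exponential.
#' @method autoplot frap_fit
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- object$data
  stopifnot(!is.null(d))
  post <- d[d$phase == "post", ]
  t0 <- min(post$time_s)
  tg <- seq(t0, max(post$time_s), length.out = 300)
  p <- object$coefficients
  curve <- tibble(time_s = tg,
                  intensity = p[["i0"]] + p[["ia"]] * (1 - exp(-(tg - t0) / p[["tau_s"]])))
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$intensity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7)
  if ("sem" %in% names(d)) {
    g <- g + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$intensity - .data$sem,
                   ymax = .data$intensity + .data$sem),
      width = 0, alpha = 0.4)
  }
  g + ggplot2::geom_line(data = curve, colour = "#d95f02", linewidth = 0.8) +
    ggplot2::labs(x = "time since bleach (s)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot an overlap time course
#'
#' @param object An `overlap_timecourse` from [build_timecourse()].
#' @param ... Ignored.
#' @return A faceted ggplot: total width, central FWHM (reliable points
#'   filled), maximum intensity and chromosome separation vs time.
#' @method autoplot overlap_timecourse
#' @export
autoplot.overlap_timecourse <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::select("time_min", "total_width_um", "central_fwhm_um",
                  "central_reliable", "max_intensity", "dna_separation_um") |>
    tidyr::pivot_longer(c("total_width_um", "central_fwhm_um",
                          "max_intensity", "dna_separation_um"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(alpha = ifelse(
      .data$metric == "central_fwhm_um" & !.data$central_reliable, 0.25, 1)),
      size = 1, show.legend = FALSE) +
    ggplot2::scale_alpha_identity() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time from anaphase onset (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Survival and position summaries of comet tracks
#'
#' @param survival Output of [survival_curve()].
#' @return A ggplot step curve of survival probability vs track duration.
#' @export
plot_survival_curve <- function(survival) {
  ggplot2::ggplot(survival, ggplot2::aes(x = .data$duration_s, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "track duration (s)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' @rdname plot_survival_curve
#' @param histogram Output of [position_histogram()].
#' @return A ggplot bar chart of comet counts along the normalized
#'   pole-to-pole axis.
#' @export
plot_position_histogram <- function(histogram) {
  ggplot2::ggplot(histogram, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = histogram$bin_hi[1] - histogram$bin_lo[1]) +
    ggplot2::labs(x = "pole-to-pole position (0 = pole 1, 1 = pole 2)",
                  y = "comet samples") +
    ggplot2::theme_minimal()
}
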
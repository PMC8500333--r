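# Bilinear sampling of img (Y x X matrix) at fractional pixel coords (x, y).
# Points outside the image are NA.
bilinear_sample <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  out <- rep(NA_real_, length(x))
  inside <- x >= 1 & x <= nx & y >= 1 & y <= ny
  xi <- x[inside]; yi <- y[inside]
  x0 <- pmin(floor(xi), nx - 1); y0 <- pmin(floor(yi), ny - 1)
  fx <- xi - x0; fy <- yi - y0
  i00 <- (x0 - 1) * ny + y0
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[i00 + ny] +
    (1 - fx) * fy * img[i00 + 1] +
    fx * fy * img[i00 + ny + 1]
  out[inside] <- v
  out
}

#' Align one frame on the spindle axis
#'
#' Translates and rotates a frame so that the midpoint between the two
#' annotated spindle poles sits at the image centre and the pole-to-pole axis
#' is horizontal. Resampling is bilinear (inverse mapping); pixels whose
#' source falls outside the field of view are `NA` (masked) and are excluded
#' from all downstream band means.
#'
#' @param frame_image Y x X numeric matrix.
#' @param pole_pair Numeric `c(x1, y1, x2, y2)` pole coordinates in pixels
#'   (x = column, y = row), inside the frame.
#' @return Aligned Y x X matrix with `NA` outside the mapped field.
#' @export
align_frame <- function(frame_image, pole_pair) {
  stopifnot(is.matrix(frame_image), length(pole_pair) == 4)
  x1 <- pole_pair[1]; y1 <- pole_pair[2]; x2 <- pole_pair[3]; y2 <- pole_pair[4]
  if (isTRUE(all.equal(c(x1, y1), c(x2, y2)))) {
    abort("coincident pole coordinates: cannot define a spindle axis.")
  }
  ny <- nrow(frame_image); nx <- ncol(frame_image)
  if (any(c(x1, x2) < 1 | c(x1, x2) > nx) || any(c(y1, y2) < 1 | c(y1, y2) > ny)) {
    abort("pole coordinates must lie inside the frame.")
  }
  mx <- (x1 + x2) / 2; my <- (y1 + y2) / 2
  th <- atan2(y2 - y1, x2 - x1)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  # identity shortcut: already horizontal and centred
  if (abs(th) < 1e-12 && abs(mx - cx) < 1e-12 && abs(my - cy) < 1e-12) {
    return(frame_image)
  }
  dx <- rep(seq_len(nx) - cx, each = ny)
  dy <- rep(seq_len(ny) - cy, times = nx)
  xs <- mx + cos(th) * dx - sin(th) * dy
  ys <- my + sin(th) * dx + cos(th) * dy
  matrix(bilinear_sample(frame_image, xs, ys), ny, nx)
}

#' Align every frame of a stack using per-frame pole annotations
#'
#' @param stack An [image_stack()].
#' @param poles Data frame with columns `frame` (0-based), `x1`, `y1`, `x2`,
#'   `y2` (pixels), one row per frame of the stack.
#' @return An aligned [image_stack()] (masked pixels `NA`).
#' @export
align_stack <- function(stack, poles) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  poles <- as.data.frame(poles)[order(poles$frame), , drop = FALSE]
  if (nrow(poles) != d[1]) abort("`poles` must have one row per frame.")
  out <- stack$data
  for (i in seq_len(d[1])) {
    pp <- as.numeric(poles[i, c("x1", "y1", "x2", "y2")])
    for (ch in seq_len(d[2])) {
      out[i, ch, , ] <- align_frame(stack$data[i, ch, , ], pp)
    }
  }
  image_stack(out, stack$pixel_size_um, stack$frame_interval_s,
              stack$channel_names)
}

#' Extract a kymograph from an aligned stack
#'
#' Each kymograph row is the per-column mean over a horizontal band of the
#' stated width centred on the spindle axis (the image centre row of an
#' aligned stack), one row per frame. Masked (`NA`) pixels are excluded from
#' the mean.
#'
#' @param aligned_stack An aligned [image_stack()].
#' @param line_width_um Band width (um); 8 um for midzone profile work,
#'   0.3 um for plus-end comet kymographs.
#' @return A [kymograph()] with one channel per stack channel.
#' @export
extract_kymograph <- function(aligned_stack, line_width_um = 8) {
  stopifnot(inherits(aligned_stack, "image_stack"))
  d <- dim(aligned_stack$data)
  p <- aligned_stack$pixel_size_um
  if (line_width_um < p) abort("line width must be at least one pixel.")
  ny <- d[3]; nx <- d[4]
  cy <- (ny + 1) / 2
  rows <- which(abs(seq_len(ny) - cy) * p <= line_width_um / 2)
  if (line_width_um / 2 > (cy - 1) * p) {
    warn(sprintf("band of %.2f um exceeds the image; clipped to %.2f um.",
                 line_width_um, (2 * (cy - 1) + 1) * p))
  }
  x_um <- (seq_len(nx) - (nx + 1) / 2) * p
  data <- lapply(seq_len(d[2]), function(ch) {
    m <- matrix(NA_real_, d[1], nx)
    for (i in seq_len(d[1])) {
      m[i, ] <- colMeans(aligned_stack$data[i, ch, rows, , drop = TRUE],
                         na.rm = TRUE)
    }
    m[is.nan(m)] <- NA_real_
    m
  })
  names(data) <- aligned_stack$channel_names
  kymograph(data, x_um = x_um,
            frame_interval_s = aligned_stack$frame_interval_s,
            pixel_size_um = p)
}

#' Mean pre-onset pole distance of a cell
#'
#' @param poles Pole annotation data frame (`frame`, `x1`, `y1`, `x2`, `y2`,
#'   pixels).
#' @param onset_frame 0-based anaphase-onset frame.
#' @param pixel_size_um Pixel size (um).
#' @return Mean pole-to-pole distance (um) over frames before onset.
#' @export
metaphase_pole_distance <- function(poles, onset_frame, pixel_size_um) {
  pre <- poles[poles$frame < onset_frame, , drop = FALSE]
  if (nrow(pre) == 0) abort("no pre-onset frames to measure the metaphase pole distance.")
  mean(sqrt((pre$x2 - pre$x1)^2 + (pre$y2 - pre$y1)^2)) * pixel_size_um
}

#' Detect anaphase onset from the DNA channel of a kymograph
#'
#' Fits the two-Gaussian DNA model to every row and returns the first frame
#' at which the fitted chromosome separation exceeds a threshold (a fraction
#' of the metaphase pole distance) and stays above it for at least `sustain`
#' consecutive frames. Because a ramped separation crosses the threshold a
#' frame or two after it actually starts, the separation ramp over the first
#' frames above threshold is extrapolated linearly back to zero separation,
#' which brings the detection within one frame of the true start and is
#' robust to spurious separations fitted to unresolved pre-onset profiles.
#'
#' @param kymo A [kymograph()] containing a DNA channel.
#' @param dna_channel Channel name of the DNA signal.
#' @param metaphase_pole_distance_um Metaphase pole distance (um); defaults to
#'   the value stored in the kymograph.
#' @param threshold_frac Separation threshold as a fraction of the metaphase
#'   pole distance.
#' @param sustain Number of consecutive frames the separation must stay above
#'   threshold.
#' @return 0-based onset frame index, or `NA_integer_` if the chromosome
#'   masses never separate.
#' @export
detect_anaphase_onset <- function(kymo, dna_channel = "dna",
                                  metaphase_pole_distance_um = NULL,
                                  threshold_frac = 0.2, sustain = 3L) {
  stopifnot(inherits(kymo, "kymograph"))
  if (!dna_channel %in% names(kymo$data)) {
    abort(sprintf("kymograph has no channel named '%s'.", dna_channel))
  }
  D_m <- metaphase_pole_distance_um %||% kymo$metaphase_pole_distance_um
  if (is.null(D_m)) abort("metaphase pole distance unknown; supply `metaphase_pole_distance_um`.")
  m <- kymo$data[[dna_channel]]
  nt <- nrow(m)
  sep <- rep(NA_real_, nt)
  for (i in seq_len(nt)) {
    prof <- tibble(x_um = kymo$x_um, intensity = m[i, ])
    fit <- try(fit_dna_profile(prof), silent = TRUE)
    if (!inherits(fit, "try-error") && isTRUE(fit$converged)) {
      sep[i] <- fit$separation
    }
  }
  if (mean(is.na(sep)) > 0.5) {
    abort("DNA profile fit failed on more than half of the frames.")
  }
  thr <- threshold_frac * D_m
  above <- !is.na(sep) & sep > thr
  run <- 0L
  first <- NA_integer_
  for (i in seq_len(nt)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= sustain) { first <- i - sustain + 1L; break }
  }
  if (is.na(first)) return(NA_integer_)
  # back-extrapolate the ramp: s is linear in frame during early separation
  ramp_idx <- first:min(first + 4L, nt)
  ramp_idx <- ramp_idx[!is.na(sep[ramp_idx])]
  onset <- first
  if (length(ramp_idx) >= 2) {
    co <- coef(lm(sep[ramp_idx] ~ ramp_idx))
    if (is.finite(co[[2]]) && co[[2]] > 0) {
      onset <- max(1, first - 2L * sustain, min(first, round(-co[[1]] / co[[2]])))
    }
  }
  as.integer(onset - 1L)  # 0-based
}

#' Average kymographs across cells
#'
#' Rescales each kymograph's axial axis to the mean metaphase pole distance
#' of the ensemble (linear interpolation onto a common grid), shifts the time
#' axis so anaphase onsets coincide, and computes the per-bin mean, count and
#' standard error across cells.
#'
#' @param kymographs List of [kymograph()] objects.
#' @param onsets Optional integer vector of 0-based onset frames overriding
#'   the values stored in the kymographs.
#' @param metaphase_distances Optional numeric vector overriding the stored
#'   metaphase pole distances (um).
#' @return An `avg_kymograph`: per-channel `mean`, `n` and `sem` matrices on a
#'   common grid, axial coordinate `x_um` (um, on the scale of the average
#'   metaphase pole distance) with normalized coordinate `x_norm = x_um / D`,
#'   and time relative to anaphase onset.
#' @export
normalize_and_average <- function(kymographs, onsets = NULL,
                                  metaphase_distances = NULL) {
  if (length(kymographs) == 0) abort("need at least one kymograph to average.")
  stopifnot(all(vapply(kymographs, inherits, TRUE, "kymograph")))
  n_cell <- length(kymographs)
  onsets <- onsets %||% vapply(kymographs, function(k) {
    if (is.null(k$onset_frame)) NA_integer_ else as.integer(k$onset_frame)
  }, 1L)
  Ds <- metaphase_distances %||% vapply(kymographs, function(k) {
    k$metaphase_pole_distance_um %||% NA_real_
  }, 1)
  if (anyNA(onsets) || anyNA(Ds)) {
    abort("every kymograph needs an onset frame and a metaphase pole distance.")
  }
  D_bar <- mean(Ds)
  dt <- unique(vapply(kymographs, `[[`, 1, "frame_interval_s"))
  if (length(dt) != 1) abort("kymographs must share one frame interval.")
  channels <- names(kymographs[[1]]$data)

  # common axial grid: finest rescaled pixel size, spanning the widest cell
  steps <- vapply(seq_len(n_cell),
                  function(i) kymographs[[i]]$pixel_size_um * D_bar / Ds[i], 1)
  half_span <- max(vapply(seq_len(n_cell), function(i) {
    max(abs(kymographs[[i]]$x_um)) * D_bar / Ds[i]
  }, 1))
  step <- min(steps)
  x_grid <- seq(-half_span, half_span, by = step)

  rel <- lapply(seq_len(n_cell), function(i) {
    seq_len(nrow(kymographs[[i]]$data[[1]])) - 1L - onsets[i]
  })
  rel_range <- range(unlist(rel))
  rel_grid <- seq(rel_range[1], rel_range[2])
  nt <- length(rel_grid); nx <- length(x_grid)

  out <- list()
  for (ch in channels) {
    s1 <- s2 <- nn <- matrix(0, nt, nx)
    for (i in seq_len(n_cell)) {
      k <- kymographs[[i]]
      xs <- k$x_um * D_bar / Ds[i]
      m <- k$data[[ch]]
      for (r in seq_len(nrow(m))) {
        ti <- match(rel[[i]][r], rel_grid)
        y <- approx(xs, m[r, ], xout = x_grid, rule = 1)$y
        ok <- !is.na(y)
        s1[ti, ok] <- s1[ti, ok] + y[ok]
        s2[ti, ok] <- s2[ti, ok] + y[ok]^2
        nn[ti, ok] <- nn[ti, ok] + 1
      }
    }
    mu <- ifelse(nn > 0, s1 / pmax(nn, 1), NA_real_)
    var_ <- ifelse(nn > 1, pmax(s2 - s1^2 / pmax(nn, 1), 0) / pmax(nn - 1, 1), 0)
    se <- ifelse(nn > 0, sqrt(var_ / pmax(nn, 1)), NA_real_)
    out[[ch]] <- list(mean = mu, n = nn, sem = se)
  }
  structure(list(
    data = out, x_um = x_grid, x_norm = x_grid / D_bar,
    rel_frame = rel_grid, time_s = rel_grid * dt,
    onset_row = which(rel_grid == 0L), frame_interval_s = dt,
    metaphase_pole_distance_um = D_bar, n_cells = n_cell
  ), class = "avg_kymograph")
}

#' @export
print.avg_kymograph <- function(x, ...) {
  cat(sprintf(
    "<avg_kymograph> %d cells, %d frames x %d bins, channels: %s\n",
    x$n_cells, length(x$rel_frame), length(x$x_um),
    paste(names(x$data), collapse = ", ")))
  cat(sprintf("  time 0 = anaphase onset; mean metaphase pole distance %.2f um\n",
              x$metaphase_pole_distance_um))
  invisible(x)
}

#' @method as_tibble avg_kymograph
#' @export
as_tibble.avg_kymograph <- function(x, ...) {
  purrr::imap_dfr(x$data, function(ch, name) {
    tibble(
      channel = name,
      time_s = rep(x$time_s, times = length(x$x_um)),
      x_um = rep(x$x_um, each = length(x$time_s)),
      intensity = as.vector(ch$mean),
      sem = as.vector(ch$sem),
      n = as.vector(ch$n)
    )
  })
}

# Mono-exponential bleaching factor per frame from total in-band intensity.
# Returns a factor vector normalized to 1 at the first frame.
bleach_factors <- function(mat, frame_interval_s) {
  tot <- rowSums(mat, na.rm = TRUE)
  t_s <- (seq_len(nrow(mat)) - 1) * frame_interval_s
  ok <- tot > 0
  if (sum(ok) < 2) return(rep(1, nrow(mat)))
  k <- -coef(lm(log(tot[ok]) ~ t_s[ok]))[[2]]
  exp(-k * t_s) / 1
}

#' Extract a background-subtracted intensity profile from a kymograph
#'
#' Returns one axial profile: a single kymograph row, or the mean over a
#' window of rows. The background (per-frame median of the outermost 10% of
#' columns, which lie off the spindle) is subtracted, and, when requested,
#' the profile is divided by a global bleaching factor obtained from a
#' mono-exponential fit to the total in-band intensity over time.
#'
#' @param kymo A [kymograph()] or `avg_kymograph`.
#' @param frames 0-based frame index, or vector of indices to average (for an
#'   `avg_kymograph`, indices are relative to onset).
#' @param channel Channel name.
#' @param subtract_background Subtract the off-spindle background estimate.
#' @param bleach_correct Divide by the fitted global bleaching factor.
#' @return Tibble `x_um`, `intensity` (+ `sem` for averaged input).
#' @export
extract_profile <- function(kymo, frames, channel = "prc1",
                            subtract_background = TRUE,
                            bleach_correct = FALSE) {
  avg <- inherits(kymo, "avg_kymograph")
  if (!avg && !inherits(kymo, "kymograph")) {
    abort("`kymo` must be a kymograph or avg_kymograph.")
  }
  m <- if (avg) kymo$data[[channel]]$mean else kymo$data[[channel]]
  if (is.null(m)) abort(sprintf("no channel named '%s'.", channel))
  idx <- if (avg) match(frames, kymo$rel_frame) else frames + 1L
  if (anyNA(idx) || any(idx < 1 | idx > nrow(m))) abort("frame index out of range.")
  bf <- if (bleach_correct) bleach_factors(m, kymo$frame_interval_s) else rep(1, nrow(m))
  nx <- ncol(m)
  n_edge <- max(1L, floor(0.05 * nx))
  edge_cols <- c(seq_len(n_edge), seq(nx - n_edge + 1L, nx))
  rows <- matrix(NA_real_, length(idx), nx)
  for (j in seq_along(idx)) {
    r <- m[idx[j], ]
    bg <- if (subtract_background) median(r[edge_cols], na.rm = TRUE) else 0
    rows[j, ] <- (r - bg) / bf[idx[j]]
  }
  out <- tibble(x_um = kymo$x_um,
                intensity = colMeans(rows, na.rm = TRUE))
  if (avg) {
    se <- kymo$data[[channel]]$sem[idx, , drop = FALSE]
    out$sem <- sqrt(colMeans(se^2, na.rm = TRUE)) / sqrt(nrow(se))
  }
  out
}

#' Rainbow-coded time projection of a movie
#'
#' Tints each frame with a colour drawn from the rainbow (red for the first
#' frame through blue for the last) and maximum-projects the tinted frames,
#' visualising motion as colour order in a single image.
#'
#' @param stack An [image_stack()].
#' @param channel Channel index or name.
#' @param n_frames Number of frames used (evenly spaced from the start;
#'   clipped to the stack length).
#' @return Y x X x 3 RGB array in `[0, 1]`.
#' @export
render_time_stack <- function(stack, channel = 1L, n_frames = 20L) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) channel <- match(channel, stack$channel_names)
  d <- dim(stack$data)
  n <- min(n_frames, d[1])
  idx <- unique(round(seq(1, d[1], length.out = n)))
  cols <- grDevices::rainbow(length(idx), start = 0, end = 0.7)
  rgb <- grDevices::col2rgb(cols) / 255
  top <- max(stack$data[idx, channel, , ], na.rm = TRUE)
  if (top <= 0) top <- 1
  out <- array(0, dim = c(d[3], d[4], 3))
  for (j in seq_along(idx)) {
    fr <- stack$data[idx[j], channel, , ] / top
    fr[is.na(fr)] <- 0
    for (k in 1:3) out[, , k] <- pmax(out[, , k], fr * rgb[k, j])
  }
  out
}
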
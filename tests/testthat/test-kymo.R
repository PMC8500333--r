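make_spot_frame <- function(ny, nx, spots, amp = 1, sigma = 1.5) {
  # spots: data.frame(x, y) in pixel coordinates
  xg <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  yg <- matrix(seq_len(ny), ny, nx)
  img <- matrix(0, ny, nx)
  for (i in seq_len(nrow(spots))) {
    img <- img + amp * exp(-((xg - spots$x[i])^2 + (yg - spots$y[i])^2) /
                             (2 * sigma^2))
  }
  img
}

test_that("alignment is the identity for a centred horizontal spindle", {
  img <- matrix(runif(61 * 81), 61, 81)
  pp <- c(21, 31, 61, 31)  # horizontal, midpoint at image centre (41, 31)
  expect_identical(align_frame(img, pp), img)
  expect_error(align_frame(img, c(10, 10, 10, 10)), "coincident")
  expect_error(align_frame(img, c(0, 5, 20, 5)), "inside the frame")
})

test_that("alignment centres and levels a rotated, offset spindle", {
  ny <- 101; nx <- 141
  th <- 30 * pi / 180
  mid <- c(75, 46)  # off-centre midpoint (x, y)
  D <- 40           # pole distance in px
  p1 <- c(mid[1] - cos(th) * D / 2, mid[2] - sin(th) * D / 2)
  p2 <- c(mid[1] + cos(th) * D / 2, mid[2] + sin(th) * D / 2)
  img <- make_spot_frame(ny, nx, data.frame(x = c(p1[1], p2[1]),
                                            y = c(p1[2], p2[2])))
  al <- align_frame(img, c(p1, p2))
  # oracle: the two pole spots must land at the centre row, +- D/2 columns
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  for (sgn in c(-1, 1)) {
    tgt_x <- cx + sgn * D / 2
    win <- al[(cy - 3):(cy + 3), round(tgt_x - 3):round(tgt_x + 3)]
    peak <- which(win == max(win, na.rm = TRUE), arr.ind = TRUE)
    expect_lt(abs(peak[1] - 4), 1.5)   # within 0.5 px of centre row + interp
    expect_lt(abs(peak[2] - (tgt_x - round(tgt_x - 3) + 1)), 1.5)
  }
  # integrated intensity preserved within 1% (masked pixels excluded)
  expect_lt(abs(sum(al, na.rm = TRUE) / sum(img) - 1), 0.01)
})

test_that("kymograph band mean equals the brute-force mean over the band", {
  ny <- 41; nx <- 60
  arr <- array(0, dim = c(3, 1, ny, nx))
  set.seed(4)
  for (t in 1:3) arr[t, 1, , ] <- matrix(runif(ny * nx), ny, nx)
  st <- image_stack(arr, pixel_size_um = 0.5, frame_interval_s = 10)
  ky <- extract_kymograph(st, line_width_um = 8)
  rows <- which(abs(seq_len(ny) - 21) * 0.5 <= 4)
  for (t in 1:3) {
    expect_equal(ky$data$ch1[t, ], colMeans(arr[t, 1, rows, ]),
                 tolerance = 1e-14)
  }
  # uniform image gives a constant kymograph
  arr2 <- array(3.7, dim = c(2, 1, ny, nx))
  ky2 <- extract_kymograph(image_stack(arr2, 0.5, 10), 8)
  expect_true(all(ky2$data$ch1 == 3.7))
  # narrow comet-tracking band still works (single row at 0.3 um < pixel)
  expect_error(extract_kymograph(st, line_width_um = 0.3), "one pixel")
  ky3 <- extract_kymograph(image_stack(arr, 0.1, 10), line_width_um = 0.3)
  rows3 <- which(abs(seq_len(ny) - 21) * 0.1 <= 0.15)
  expect_equal(ky3$data$ch1[1, ],
               colMeans(matrix(arr[1, 1, rows3, ], nrow = length(rows3))),
               tolerance = 1e-14)
  # band wider than the image warns and clips
  expect_warning(extract_kymograph(st, line_width_um = 100), "clipped")
})

test_that("anaphase onset is detected within one frame of the true ramp start", {
  nt <- 60; onset <- 40
  x <- seq(-12, 12, by = 0.2)
  dna <- t(vapply(seq_len(nt) - 1, function(f) {
    sep <- max(0, (f - onset + 1)) * 1.2  # ramp starts at frame `onset`
    profile_eval(dna_model(1, 0, sep, 1.5), x)
  }, numeric(length(x))))
  ky <- kymograph(list(dna = dna), x_um = x, frame_interval_s = 30,
                  pixel_size_um = 0.2, metaphase_pole_distance_um = 8)
  expect_equal(detect_anaphase_onset(ky), 40L, tolerance = 1)
  # chromosomes that never separate yield no onset
  dna0 <- t(vapply(seq_len(20), function(f) {
    profile_eval(dna_model(1, 0, 0, 1.5), x)
  }, numeric(length(x))))
  ky0 <- kymograph(list(dna = dna0), x_um = x, frame_interval_s = 30,
                   pixel_size_um = 0.2, metaphase_pole_distance_um = 8)
  expect_true(is.na(detect_anaphase_onset(ky0)))
})

test_that("onset detection matches generator truth under noise", {
  cfg <- spindle_sim_config(noise_model = "gaussian", noise_sd = 0.1, seed = 3L)
  sim <- generate_spindle_kymograph(cfg)
  truth_onset <- min(sim$truth$frame[sim$truth$phase == "anaphase"])
  det <- detect_anaphase_onset(sim$kymo)
  expect_lte(abs(det - truth_onset), 1)
})

test_that("averaging identical kymographs returns the kymograph with zero SEM", {
  cfg <- small_movie_config()
  ky <- generate_spindle_kymograph(cfg)$kymo
  avg <- normalize_and_average(list(ky, ky, ky))
  on_rows <- avg$rel_frame + ky$onset_frame + 1L
  keep <- which(avg$x_um >= min(ky$x_um) & avg$x_um <= max(ky$x_um))
  # interpolate one original row onto the common grid as the oracle
  r <- 3L
  oracle <- approx(ky$x_um, ky$data$prc1[r, ], xout = avg$x_um[keep])$y
  ti <- which(avg$rel_frame == (r - 1L) - ky$onset_frame)
  expect_equal(avg$data$prc1$mean[ti, keep], oracle, tolerance = 1e-10)
  expect_lt(max(avg$data$prc1$sem, na.rm = TRUE), 1e-6)
  expect_equal(unique(as.vector(avg$data$prc1$n[ti, keep])), 3)
})

test_that("averaging aligns shifted onsets and is permutation invariant", {
  cfg <- small_movie_config()
  ky <- generate_spindle_kymograph(cfg)$kymo
  shift <- function(k, s) {
    k2 <- k
    for (ch in names(k2$data)) {
      m <- k2$data[[ch]]
      k2$data[[ch]] <- rbind(m[rep(1, s), , drop = FALSE],
                             m[seq_len(nrow(m) - s), , drop = FALSE])
    }
    k2$onset_frame <- k$onset_frame + s
    k2
  }
  ky2 <- shift(ky, 2L)
  avg <- normalize_and_average(list(ky, ky2))
  common <- intersect(seq_len(nrow(ky$data$prc1)) - 1L - ky$onset_frame,
                      seq_len(nrow(ky2$data$prc1)) - 1L - ky2$onset_frame)
  keep <- which(avg$x_um >= min(ky$x_um) & avg$x_um <= max(ky$x_um))
  for (rf in range(common)) {
    ti <- which(avg$rel_frame == rf)
    oracle <- approx(ky$x_um, ky$data$prc1[rf + ky$onset_frame + 1L, ],
                     xout = avg$x_um[keep])$y
    expect_equal(avg$data$prc1$mean[ti, keep], oracle, tolerance = 1e-10)
  }
  avg_rev <- normalize_and_average(list(ky2, ky))
  expect_equal(avg$data$prc1$mean, avg_rev$data$prc1$mean, tolerance = 1e-12)
  expect_error(normalize_and_average(list()), "at least one")
})

test_that("profile extraction subtracts background and undoes bleaching", {
  cfg <- small_movie_config(background = 0)
  ky <- generate_spindle_kymograph(cfg)$kymo
  # zero background, bleach-free: profile equals the raw row
  p <- extract_profile(ky, 0, channel = "prc1", subtract_background = FALSE)
  expect_equal(p$intensity, ky$data$prc1[1, ], tolerance = 1e-14)
  # background subtraction shifts by the per-frame edge median only
  pb <- extract_profile(ky, 0, channel = "prc1", subtract_background = TRUE)
  expect_equal(length(unique(round(p$intensity - pb$intensity, 12))), 1)
  # known exponential bleaching: corrected amplitude time-invariant within 1%
  k_b <- 0.002
  cfgb <- spindle_sim_config(bleach_rate_per_s = k_b)
  kyb <- generate_spindle_kymograph(cfgb)$kymo
  nt <- nrow(kyb$data$prc1)
  a0 <- max(extract_profile(kyb, 0, channel = "prc1",
                            bleach_correct = TRUE)$intensity)
  # compare metaphase frames only (amplitude is scheduled constant there)
  on <- kyb$onset_frame
  a1 <- max(extract_profile(kyb, on - 1L, channel = "prc1",
                            bleach_correct = TRUE)$intensity)
  raw1 <- max(extract_profile(kyb, on - 1L, channel = "prc1")$intensity)
  expect_lt(abs(a1 / a0 - 1), 0.01)
  expect_gt(abs(raw1 / a0 - 1), 0.05)  # uncorrected clearly decays
})

test_that("kymographs respect the reflection symmetry of the input movie", {
  cfg <- small_movie_config(noise_model = "gaussian", noise_sd = 0.05,
                            seed = 17L)
  sim <- generate_spindle_movie(cfg)
  st <- sim$stack
  ky <- extract_kymograph(st, 8)
  # reflect the movie about the (vertical) axis through the spindle midpoint
  refl <- st
  refl$data <- st$data[, , , rev(seq_len(dim(st$data)[4])), drop = FALSE]
  kyr <- extract_kymograph(refl, 8)
  expect_equal(kyr$data$prc1, ky$data$prc1[, rev(seq_len(ncol(ky$data$prc1)))],
               tolerance = 1e-12)
})

test_that("rainbow time projection orders spot hues with time", {
  ny <- 31; nx <- 95
  arr <- array(0, dim = c(20, 1, ny, nx))
  xs <- round(seq(6, nx - 6, length.out = 20))
  for (t in 1:20) arr[t, 1, , ] <- make_spot_frame(ny, nx,
                                                   data.frame(x = xs[t], y = 16))
  st <- image_stack(arr, 0.1, 1)
  rgb <- render_time_stack(st, n_frames = 20)
  hues <- vapply(seq_along(xs), function(i) {
    px <- rgb[16, xs[i], ]
    grDevices::rgb2hsv(px[1], px[2], px[3], maxColorValue = 1)[1, 1]
  }, 1)
  expect_true(all(diff(hues) > 0))  # red (0) towards blue (~0.7)
  expect_lt(hues[1], 0.05)
  # single frame: tinted at the red end
  rgb1 <- render_time_stack(image_stack(arr[1, 1, , , drop = FALSE], 0.1, 1),
                            n_frames = 20)
  expect_gt(max(rgb1[, , 1]), 0.99)
  expect_equal(max(rgb1[, , 3]), 0)
})

test_that("metaphase pole distance averages the pre-onset annotation", {
  poles <- data.frame(frame = 0:4, x1 = c(10, 10, 11, 10, 10), y1 = 20,
                      x2 = c(50, 50, 51, 50, 50), y2 = 20)
  expect_equal(metaphase_pole_distance(poles, 3, 0.2), 40 * 0.2)
  expect_error(metaphase_pole_distance(poles, 0, 0.2), "no pre-onset")
})
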
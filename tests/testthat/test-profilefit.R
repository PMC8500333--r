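x_fine <- seq(-16, 16, by = 0.1)

test_that("FWHM/sigma conversion is exact", {
  expect_equal(sigma_to_fwhm(2), 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-15)
  expect_equal(fwhm_to_sigma(sigma_to_fwhm(1.234)), 1.234, tolerance = 1e-15)
  expect_equal(sigma_to_fwhm(2), 4.70964, tolerance = 1e-6)
})

test_that("metaphase Gaussian fit recovers noiseless parameters exactly", {
  p <- generate_profile(metaphase_model(1, 0, 2, 0), seq(-10, 10, by = 0.1))
  f <- fit_metaphase_profile(p)
  expect_equal(unname(f$coefficients),
               c(1, 0, 2, 0), tolerance = 1e-8)
  expect_equal(f$fwhm_um, 4.70964, tolerance = 1e-5)
  # the published metaphase spindle length round-trips through the fit
  p8 <- generate_profile(metaphase_model(1, 0, fwhm_to_sigma(8), 0.1), x_fine)
  expect_equal(fit_metaphase_profile(p8)$fwhm_um, 8, tolerance = 1e-8)
  expect_error(fit_metaphase_profile(p8[1:4, ]), "at least 6")
})

test_that("metaphase fit is accurate under noise: Monte-Carlo on 100 replicates", {
  truth_sigma <- fwhm_to_sigma(8)
  errs <- vapply(seq_len(100), function(s) {
    p <- generate_profile(metaphase_model(1, 0, truth_sigma, 0), x_fine,
                          noise_sd = 0.02, seed = 1000L + s)
    abs(fit_metaphase_profile(p)$coefficients[["sigma"]] - truth_sigma) /
      truth_sigma
  }, 1)
  expect_lt(median(errs), 0.02)
})

test_that("anaphase fit recovers the published profile geometry exactly", {
  # parameters solved so that L = 1.700 um and W = 20.0 um
  a <- anaphase_for(W = 20, L = 1.7, amp_c = 5, amp_s = 1, sigma_s = 0.9)
  p <- generate_profile(a, x_fine)
  f <- fit_anaphase_profile(p)
  expect_equal(f$central_fwhm_um, 1.7, tolerance = 1e-8)
  expect_equal(f$total_width_um, 20, tolerance = 1e-8)
  expect_equal(f$coefficients[["sigma_c"]], 0.72194, tolerance = 1e-4)
  expect_equal(f$coefficients[["amp_c"]], 5, tolerance = 1e-8)
  expect_equal(f$coefficients[["amp_s"]], 1, tolerance = 1e-8)
  expect_true(f$reliable)
  expect_false(f$fallback)
})

test_that("anaphase fit is mirror symmetric", {
  a <- anaphase_for(W = 14, L = 2.5, amp_c = 3, amp_s = 1.2, sigma_s = 1.1)
  p <- generate_profile(a, x_fine, noise_sd = 0.03, seed = 9L)
  f1 <- fit_anaphase_profile(p)
  p2 <- p
  p2$x_um <- rev(-p2$x_um); p2$intensity <- rev(p2$intensity)
  f2 <- fit_anaphase_profile(p2)
  for (term in c("sigma_c", "sigma_s", "d", "amp_c", "amp_s", "baseline")) {
    expect_equal(f1$coefficients[[term]], f2$coefficients[[term]],
                 tolerance = 1e-6)
  }
  expect_equal(f1$coefficients[["x0"]], -f2$coefficients[["x0"]],
               tolerance = 1e-6)
})

test_that("constrained fit equals an unconstrained 3-Gaussian fit on constrained data", {
  a <- anaphase_for(W = 18, L = 2.2, amp_c = 4, amp_s = 1, sigma_s = 1)
  p <- generate_profile(a, x_fine)
  f <- fit_anaphase_profile(p)
  # oracle: 9-parameter unconstrained sum of three Gaussians
  eval_free <- deriv(
    ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) + a2 * exp(-(x - m2)^2 / (2 * s2^2)) +
      a3 * exp(-(x - m3)^2 / (2 * s3^2)) + b,
    c("a1", "m1", "s1", "a2", "m2", "s2", "a3", "m3", "s3", "b"),
    function.arg = c("a1", "m1", "s1", "a2", "m2", "s2", "a3", "m3", "s3",
                     "b", "x"))
  free <- midzone:::try_ls(
    eval_free,
    start = c(a1 = 3, m1 = 0, s1 = 1, a2 = 0.8, m2 = -8, s2 = 1.2,
              a3 = 0.8, m3 = 8, s3 = 1.2, b = 0),
    lower = c(0, -16, 0.05, 0, -16, 0.05, 0, -16, 0.05, -Inf),
    upper = c(Inf, 16, 32, Inf, 16, 32, Inf, 16, 32, Inf),
    x = p$x_um, y = p$intensity)
  expect_equal(f$coefficients[["amp_c"]], free$par[["a1"]], tolerance = 1e-6)
  expect_equal(f$coefficients[["sigma_c"]], free$par[["s1"]], tolerance = 1e-6)
  expect_equal(free$par[["m3"]] - free$par[["m2"]],
               2 * f$coefficients[["d"]], tolerance = 1e-5)
  expect_equal(free$par[["a2"]], free$par[["a3"]], tolerance = 1e-6)
})

test_that("degenerate anaphase profiles fall back to a single Gaussian", {
  p <- generate_profile(metaphase_model(2, 0, 3, 0.05), x_fine)
  f <- fit_anaphase_profile(p)
  expect_false(f$reliable)
  expect_equal(glance(f)$central_fwhm_um, sigma_to_fwhm(3), tolerance = 1e-4)
})

test_that("fits are invariant to affine intensity rescaling", {
  a <- anaphase_for(W = 16, L = 2, amp_c = 2, amp_s = 0.7)
  p <- generate_profile(a, x_fine, noise_sd = 0.02, seed = 4L)
  f1 <- fit_anaphase_profile(p)
  p2 <- p; p2$intensity <- 3.5 * p$intensity + 0.8
  f2 <- fit_anaphase_profile(p2)
  for (term in c("x0", "sigma_c", "d", "sigma_s")) {
    expect_equal(f1$coefficients[[term]], f2$coefficients[[term]],
                 tolerance = 1e-6)
  }
  expect_equal(f2$coefficients[["amp_c"]], 3.5 * f1$coefficients[["amp_c"]],
               tolerance = 1e-6)
  expect_equal(f2$coefficients[["baseline"]],
               3.5 * f1$coefficients[["baseline"]] + 0.8, tolerance = 1e-6)
  expect_equal(f2$central_fwhm_um, f1$central_fwhm_um, tolerance = 1e-6)
})

test_that("W >= L whenever the anaphase fit is reliable", {
  for (s in 1:20) {
    W <- withr::with_seed(s, runif(1, 10, 22))
    L <- withr::with_seed(s + 50, runif(1, 1.2, 4))
    p <- generate_profile(anaphase_for(W = W, L = L), x_fine,
                          noise_sd = 0.05, seed = s)
    f <- fit_anaphase_profile(p)
    if (isTRUE(f$reliable)) {
      expect_gte(f$total_width_um, f$central_fwhm_um)
    }
  }
})

test_that("DNA fit separates the chromosome masses", {
  # noiseless pair at +-5 um: separation exactly 10
  p <- generate_profile(dna_model(1, 0, 10, 1), x_fine)
  f <- fit_dna_profile(p)
  expect_equal(f$separation, 10, tolerance = 1e-10)
  expect_true(f$resolved)
  # unresolved masses are flagged with a floored SE
  pu <- generate_profile(dna_model(1, 0, 0.5, 1.5), x_fine,
                         noise_sd = 0.01, seed = 2L)
  fu <- fit_dna_profile(pu)
  expect_false(fu$resolved)
  expect_gte(fu$separation_se, fu$coefficients[["sigma"]] / 2)
  # generator schedule round trip, noiseless, within 1%
  cfg <- spindle_sim_config()
  sim <- generate_spindle_kymograph(cfg)
  i <- nrow(sim$truth) - 4L
  prof <- extract_profile(sim$kymo, i, channel = "dna")
  fd <- fit_dna_profile(prof)
  expect_lt(abs(fd$separation - sim$truth$dna_separation_um[i + 1]) /
              sim$truth$dna_separation_um[i + 1], 0.01)
})

test_that("chromosome separation tracks spindle elongation on coupled schedules", {
  tr <- spindle_truth(spindle_sim_config())
  el <- tr[tr$phase == "anaphase" & tr$time_from_onset_min <= 5, ]
  expect_gt(cor(el$dna_separation_um, el$pole_distance_um), 0.95)
})

test_that("maximum peak intensity is the 5-point window mean", {
  prof <- tibble::tibble(x_um = 1:5, intensity = c(1, 2, 5, 2, 1))
  expect_equal(as.numeric(max_peak_intensity(prof)), 2.2)
  const <- tibble::tibble(x_um = 1:9, intensity = rep(3.3, 9))
  expect_warning(mx <- max_peak_intensity(const), "clipped")
  expect_equal(as.numeric(mx), 3.3)
  # brute-force oracle on 50 random profiles
  for (s in 1:50) {
    y <- withr::with_seed(s, runif(31))
    prof <- tibble::tibble(x_um = seq_len(31), intensity = y)
    i <- which.max(y)
    win <- y[max(1, i - 2):min(31, i + 2)]
    expect_equal(as.numeric(suppressWarnings(max_peak_intensity(prof))),
                 mean(win))
  }
})

test_that("overlap decay fit recovers its generating parameters", {
  t_min <- seq(3, 11, by = 0.5)
  L <- 1.7 + (6 - 1.7) * exp(-(t_min - 3) / 2)
  tc <- tibble::tibble(time_min = t_min, central_fwhm_um = L,
                       central_reliable = TRUE)
  f <- fit_overlap_decay(tc)
  expect_equal(unname(f$coefficients), c(6, 1.7, 2), tolerance = 1e-8)
  expect_equal(predict(f, 3), 6, tolerance = 1e-8)
  expect_equal(predict(f, 1),
               1.7 + 4.3 * exp(-(1 - 3) / 2), tolerance = 1e-8)  # extrapolation
  # constant series: delta L = 0 and the constant is returned everywhere
  fc <- fit_overlap_decay(tibble::tibble(time_min = t_min,
                                         central_fwhm_um = rep(2, length(t_min)),
                                         central_reliable = TRUE))
  expect_true(fc$flat)
  expect_equal(fc$delta_L, 0)
  expect_equal(predict(fc, c(0, 5)), c(2, 2))
  expect_error(fit_overlap_decay(tc[1:3, ]), "at least 4")
})

test_that("fit objects expose tidy() and glance() summaries", {
  p <- generate_profile(metaphase_model(1, 0, 2, 0), seq(-8, 8, by = 0.2),
                        noise_sd = 0.01, seed = 5L)
  f <- fit_metaphase_profile(p)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("amp", "x0", "sigma", "baseline"))
  expect_true(all(td$std.error > 0))
  expect_true(glance(f)$converged)
  g <- glance(fit_anaphase_profile(generate_profile(anaphase_for(), x_fine)))
  expect_true(g$reliable)
  expect_s3_class(autoplot(f), "ggplot")
})
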
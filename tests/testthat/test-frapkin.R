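mk_curve <- function(roi, phase, time_s = seq_along(roi), reference = NULL) {
  out <- tibble::tibble(curve_id = 1L, time_s = time_s, phase = phase,
                        roi = roi)
  if (!is.null(reference)) out$reference <- reference
  out
}

test_that("normalization divides by the last-4 pre-bleach mean", {
  cv <- mk_curve(c(90, 100, 110, 100, 40, 50, 60, 65, 70, 72),
                 c(rep("pre", 4), "bleach", rep("post", 5)))
  nm <- normalize_frap(cv)
  expect_equal(nm$intensity[5], 0.40)
  expect_equal(mean(nm$intensity[1:4]), 1)
  # scale invariance
  cv2 <- cv; cv2$roi <- cv$roi * 17.3
  expect_equal(normalize_frap(cv2)$intensity, nm$intensity, tolerance = 1e-14)
  # idempotence
  expect_equal(normalize_frap(nm)$intensity, nm$intensity, tolerance = 1e-14)
  # too few pre-bleach points
  expect_error(normalize_frap(cv[3:10, ]), "fewer than 4")
  # brute-force oracle on random records
  for (s in 1:50) {
    roi <- withr::with_seed(s, runif(15, 10, 200))
    cv3 <- mk_curve(roi, c(rep("pre", 6), "bleach", rep("post", 8)))
    expect_equal(normalize_frap(cv3)$intensity, roi / mean(roi[3:6]),
                 tolerance = 1e-14)
  }
})

test_that("reference-region correction inverts a known bleaching factor", {
  t_s <- c(-(5:1) * 2, 0, seq(2, 60, by = 2))
  phase <- c(rep("pre", 5), "bleach", rep("post", 30))
  tp <- pmax(t_s - 2, 0)
  ideal <- c(rep(1, 5), 0.3, 0.3 + 0.4 * (1 - exp(-(seq(2, 60, by = 2) - 2) / 8)))
  k <- 0.005
  bleach <- exp(-k * (t_s - t_s[1]))
  cv <- mk_curve(ideal * bleach, phase, t_s, reference = bleach)
  corr <- bleach_correct(cv)
  expect_equal(corr$intensity, ideal, tolerance = 1e-12)
  # constant reference leaves the curve unchanged
  cv2 <- mk_curve(ideal, phase, t_s, reference = rep(2, length(t_s)))
  expect_equal(bleach_correct(cv2)$intensity, ideal, tolerance = 1e-12)
  # nonpositive reference rejected
  bad <- cv; bad$reference[3] <- 0
  expect_error(bleach_correct(bad), "strictly positive")
})

test_that("recovery fit is exact on a noiseless model curve", {
  fs <- generate_frap_curves(10, 0.5, i0 = 0.5, n_curves = 1, noise_sd = 0,
                             seed = 1L)
  f <- fs$curves |> normalize_frap() |> fit_recovery()
  expect_equal(f$coefficients[["i0"]], 0.5, tolerance = 1e-9)
  expect_equal(f$coefficients[["ia"]], 0.25, tolerance = 1e-9)
  expect_equal(f$coefficients[["tau_s"]], 10, tolerance = 1e-8)
  expect_equal(f$mf, 0.50, tolerance = 1e-9)
  expect_equal(f$ie, 0.75, tolerance = 1e-9)
  expect_false(f$window_limited)
})

test_that("recovery fit agrees with an exhaustive grid search on a noisy curve", {
  fs <- generate_frap_curves(30, 0.6, i0 = 0.3, n_curves = 1, noise_sd = 0.02,
                             seed = 1L)
  nm <- normalize_frap(fs$curves)
  post <- nm[nm$phase == "post", ]
  t <- post$time_s - min(post$time_s)
  g <- grid_search_frap(t, post$intensity)
  f <- fit_recovery(nm)
  expect_equal(f$coefficients[["i0"]], g[["i0"]], tolerance = 1e-3)
  expect_equal(f$coefficients[["ia"]], g[["ia"]], tolerance = 1e-3)
  expect_equal(f$coefficients[["tau_s"]], g[["tau"]], tolerance = 1e-3)
})

test_that("recovery estimation is nearly unbiased across the published tau range", {
  # Monte-Carlo bias at the ensemble workflow (n = 15 curves, SD 0.02)
  for (cfg in list(list(tau = 1.3, dt = 0.5, dur = 30),
                   list(tau = 6, dt = 2, dur = 180),
                   list(tau = 44, dt = 2, dur = 180))) {
    taus <- vapply(1:8, function(s) {
      sim <- generate_frap_curves(cfg$tau, 0.5, n_curves = 15,
                                  frame_interval_s = cfg$dt,
                                  duration_s = cfg$dur, noise_sd = 0.02,
                                  seed = 7000L + s)
      f <- sim$curves |> normalize_frap() |> average_frap_curves() |>
        fit_recovery()
      f$coefficients[["tau_s"]]
    }, 1)
    expect_lt(abs(mean(taus) - cfg$tau) / cfg$tau, 0.03)
  }
  # tau at or beyond the observation window must trip the flagged-fit path
  sim <- generate_frap_curves(124, 0.27, n_curves = 15, noise_sd = 0.02,
                              seed = 77L)
  f <- sim$curves |> normalize_frap() |> average_frap_curves() |> fit_recovery()
  expect_true(f$window_limited)
  expect_gt(f$se[["tau_s"]], 0)
})

test_that("curve averaging matches brute force and preserves identical curves", {
  fs <- generate_frap_curves(10, 0.5, n_curves = 6, noise_sd = 0.05, seed = 3L)
  nm <- normalize_frap(fs$curves)
  avg <- average_frap_curves(nm, stage = "mid_anaphase")
  wide <- matrix(nm$intensity, ncol = 6)
  expect_equal(avg$intensity, rowMeans(wide), tolerance = 1e-12)
  expect_equal(avg$sd, apply(wide, 1, sd), tolerance = 1e-12)
  expect_equal(avg$sem, apply(wide, 1, sd) / sqrt(6), tolerance = 1e-12)
  expect_equal(attr(avg, "n_cells"), 6)
  # identical curves: mean is the curve, SD is zero
  one <- nm[nm$curve_id == 1, ]
  dup <- dplyr::bind_rows(one, dplyr::mutate(one, curve_id = 2L))
  avg2 <- average_frap_curves(dup)
  expect_equal(avg2$intensity, one$intensity, tolerance = 1e-12)
  expect_true(all(avg2$sd < 1e-12))
  expect_error(average_frap_curves(nm[0, ]), "no curves")
})

test_that("published per-stage cell counts meet the n >= 12 criterion for PRC1", {
  pre <- frap_stage_presets()
  expect_true(all(pre$n_cells[pre$protein == "PRC1"] >= 12))
})

test_that("stage classification is deterministic and matches scripted stages", {
  x <- seq(-16, 16, by = 0.1)
  scripted <- list(
    metaphase = list(sep = 0, prc1 = metaphase_model(1, 0, fwhm_to_sigma(8))),
    early_anaphase = list(sep = 2, prc1 = anaphase_for(W = 10, L = 4.5,
                                                       amp_c = 1, amp_s = 0.9)),
    mid_anaphase = list(sep = 6, prc1 = anaphase_for(W = 14, L = 3.2,
                                                     amp_c = 2, amp_s = 0.8)),
    late_anaphase = list(sep = 10, prc1 = anaphase_for(W = 19, L = 2.7,
                                                       amp_c = 3, amp_s = 0.6)),
    telophase = list(sep = 12, prc1 = anaphase_for(W = 20, L = 1.7,
                                                   amp_c = 5, amp_s = 0.5))
  )
  for (stage in names(scripted)) {
    sc <- scripted[[stage]]
    pf <- if (inherits(sc$prc1, "profile_model") && sc$prc1$kind == "metaphase") {
      fit_metaphase_profile(generate_profile(sc$prc1, x))
    } else {
      fit_anaphase_profile(generate_profile(sc$prc1, x))
    }
    df <- fit_dna_profile(generate_profile(dna_model(1, 0, sc$sep, 1.5), x))
    expect_equal(as.character(classify_stage(pf, df)), stage)
  }
  # contradictory evidence: metaphase DNA with a compact anaphase profile
  pf_compact <- fit_anaphase_profile(
    generate_profile(anaphase_for(W = 20, L = 1.7, amp_c = 5, amp_s = 0.5), x))
  df_meta <- fit_dna_profile(generate_profile(dna_model(1, 0, 0, 1.5), x))
  expect_equal(as.character(classify_stage(pf_compact, df_meta)), "unknown")
})

test_that("recovery time ordering PRC1 > KIF4A > CLASP1 is reproduced at matched stages", {
  pre <- frap_stage_presets()
  rec <- function(protein, stage, dt = 2, dur = 180, n = 10, seed) {
    row <- pre[pre$protein == protein & pre$stage == stage, ]
    sim <- generate_frap_curves(row$tau_s, row$mf, n_curves = n,
                                frame_interval_s = dt, duration_s = dur,
                                noise_sd = 0.02, seed = seed)
    f <- sim$curves |> normalize_frap() |> average_frap_curves() |>
      fit_recovery()
    f$coefficients[["tau_s"]]
  }
  for (stage in c("late_anaphase", "telophase")) {
    tau_prc1 <- rec("PRC1", stage, seed = 301L)
    tau_kif <- rec("KIF4A", stage, seed = 302L)
    tau_clasp <- rec("CLASP1", stage, dt = 0.5, dur = 60, seed = 303L)
    expect_gt(tau_prc1, tau_kif)
    expect_gt(tau_kif, tau_clasp)
  }
})

test_that("mf is invariant under raw-intensity rescaling", {
  fs <- generate_frap_curves(15, 0.6, n_curves = 1, noise_sd = 0.01, seed = 8L)
  f1 <- fs$curves |> normalize_frap() |> fit_recovery()
  scaled <- fs$curves; scaled$roi <- scaled$roi * 42
  f2 <- scaled |> normalize_frap() |> fit_recovery()
  expect_equal(f1$mf, f2$mf, tolerance = 1e-6)
  expect_equal(f1$coefficients[["tau_s"]], f2$coefficients[["tau_s"]],
               tolerance = 1e-6)
})
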
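# Shared fixtures and independent oracles used across the test files.

K_FWHM <- 2 * sqrt(2 * log(2))

# Anaphase model whose total width W = 2 d + K sigma_s and central FWHM L
# are set exactly.
anaphase_for <- function(W = 20, L = 1.7, amp_c = 5, amp_s = 1,
                         sigma_s = 0.9, baseline = 0) {
  anaphase_model(amp_c = amp_c, x0 = 0, sigma_c = L / K_FWHM, amp_s = amp_s,
                 d = (W - K_FWHM * sigma_s) / 2, sigma_s = sigma_s,
                 baseline = baseline)
}

# Iteratively refined exhaustive grid search minimizing the FRAP SSR;
# independent of the Levenberg-Marquardt path.
grid_search_frap <- function(t, y, rounds = 18, n_grid = 17) {
  lims <- list(i0 = c(0, 1), ia = c(0, 1.5), tau = c(min(diff(t)), 10 * max(t)))
  best <- NULL
  for (r in seq_len(rounds)) {
    g <- expand.grid(i0 = seq(lims$i0[1], lims$i0[2], length.out = n_grid),
                     ia = seq(lims$ia[1], lims$ia[2], length.out = n_grid),
                     tau = seq(lims$tau[1], lims$tau[2], length.out = n_grid))
    ssr <- vapply(seq_len(nrow(g)), function(i) {
      sum((y - (g$i0[i] + g$ia[i] * (1 - exp(-t / g$tau[i]))))^2)
    }, 1)
    best <- g[which.min(ssr), ]
    # halve each window, centred on the incumbent: slow enough not to lose
    # the optimum along the correlated ia-tau valley
    for (p in c("i0", "ia", "tau")) {
      half <- diff(lims[[p]]) / 4
      lims[[p]] <- c(max(lims[[p]][1], best[[p]] - half),
                     min(lims[[p]][2], best[[p]] + half))
    }
  }
  unlist(best)
}

# Small, fast spindle simulation used where the full default would be slow.
small_movie_config <- function(...) {
  spindle_sim_config(duration_min = 2, frame_interval_s = 30,
                     pixel_size_um = 0.2, image_shape = c(71L, 161L),
                     anaphase_onset_min = 1, ...)
}
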
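# midzone

Quantitative analysis of central-spindle reorganization during mitosis from
live-cell fluorescence imaging.

During anaphase the mitotic spindle elongates while antiparallel microtubule
overlaps — marked by the crosslinker PRC1 — compact into a short midzone
bundle. `midzone` implements the image-analysis pipeline used to quantify
this process in gene-edited human cells, for cell biologists who have
two-channel (midzone protein + DNA) time-lapse movies, FRAP recordings, or
plus-end comet trajectories and want the standard midzone metrics:

* **Kymographs** — per-cell space–time maps along the manually annotated
  pole-to-pole axis (translate/rotate alignment, 8 µm-wide band average),
  and cross-cell average kymographs with the spatial axis normalized to the
  mean metaphase centrosome distance and the time axis aligned at anaphase
  onset (detected from the DNA channel).
* **Profile fits** — the metaphase profile is a single Gaussian whose FWHM
  (= 2√(2 ln 2) σ) is the metaphase spindle length; the anaphase profile is
  a constrained sum of one central Gaussian and two equidistant side
  Gaussians of identical height and width:

  I(x) = A_c e^{−(x−x₀)²/2σ_c²} + A_s e^{−(x−x₀+d)²/2σ_s²} + A_s e^{−(x−x₀−d)²/2σ_s²} + b

  The central FWHM `L = 2√(2 ln 2) σ_c` is the antiparallel overlap length
  and `W = 2d + 2√(2 ln 2) σ_s` (side-peak separation plus one side FWHM)
  is the total profile width, i.e. spindle length. DNA profiles are two
  identical displaced Gaussians giving the chromosome separation. A
  mono-exponential `L(t) = L_∞ + (L₀ − L_∞) e^{−(t−t_ref)/τ_L}` is fitted to
  the overlap-length time course.
* **FRAP kinetics** — normalization to the last four pre-bleach points,
  optional reference-region photobleaching correction, per-stage curve
  averaging, and the mono-exponential recovery fit
  `I(t) = I₀ + I_a (1 − e^{−t/τ})` with recovery time τ and recovery
  fraction `m_f = I_a / (1 − I₀)`.
* **Plus-end comets** — minimum-track-length filtering (≥ 3 frames),
  internal/external classification relative to the poles, first-to-last
  endpoint speeds, per-stage median ± SEM, survival curves of track
  duration, and position histograms along the normalized pole-to-pole axis.
* **Synthetic data with ground truth** — a fully seeded forward model of an
  elongating spindle (8 → 20 µm poles, overlap FWHM decaying to 1.7 µm,
  rising central intensity, separating DNA masses, photobleaching,
  Gaussian/Poisson noise), FRAP ensembles, and comet track sets, so every
  pipeline stage can be validated by parameter recovery without any raw
  microscopy data.

All user-facing functions take and return tibbles (or light S3 containers
with `as_tibble()` methods); fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

Simulate a late-anaphase FRAP ensemble (recovery time 44 s, recovery
fraction 0.34 as ground truth), run the pipeline, and inspect the fit:

```r
library(midzone)

sim <- generate_frap_curves(tau_s = 44, mf = 0.34, n_curves = 15, seed = 7)
fit <- sim$curves |> normalize_frap() |> average_frap_curves() |> fit_recovery()
glance(fit)[, c("tau_s", "tau_se", "mf", "mf_se", "window_limited")]
#> # A tibble: 1 × 5
#>   tau_s tau_se    mf   mf_se window_limited
#>   <dbl>  <dbl> <dbl>   <dbl> <lgl>
#> 1  46.2  0.953 0.346 0.00196 FALSE
```

The fitted recovery time (46.2 ± 1.0 s) and mobile fraction (0.346 ± 0.002)
recover the generating 44 s / 0.34 from 15 noisy curves; `window_limited`
would flag recovery times too slow for the 3-minute observation window.

The full imaging pipeline, on a synthetic whole-mitosis movie:

```r
cfg <- spindle_sim_config()                       # 8 -> 20 µm spindle, L -> 1.7 µm
tc  <- build_timecourse(generate_spindle_kymograph(cfg)$kymo)
tail(tc[, c("time_min", "total_width_um", "central_fwhm_um", "dna_separation_um")], 3)
#>   time_min total_width_um central_fwhm_um dna_separation_um
#> 1      9               20            1.75              13.2
#> 2      9.5             20            1.74              13.4
#> 3     10               20            1.73              13.5
fit_overlap_decay(tc)
#> <overlap_decay_fit>
#>   L(t) = 1.7 + (3.731 - 1.7) exp(-(t - 1.5)/2)  [um, min]
```

Spindle length plateaus at the configured 20 µm while the overlap length
converges on its 1.7 µm asymptote, recovered exactly by the decay fit.

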
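---
title: "Models and methods behind midzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind midzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midzone)
```

`midzone` quantifies how the central spindle reorganizes over mitosis from
fluorescence time-lapse data: the spindle elongates, antiparallel
microtubule overlaps (marked by a PRC1-like crosslinker) compact into a
short midzone bundle, and the binding/unbinding turnover of midzone
proteins slows down. This vignette explains the models the package fits,
the forward model its synthetic-data generator implements, the numerical
choices, and the limits of what the synthetic validation can show.

## Profile models

All axial intensity profiles are functions of the signed pole-to-pole
coordinate *x* (µm, origin at the spindle midpoint).

**Metaphase.** The crosslinker decorates bundles throughout the spindle, so
the profile is well described by a single Gaussian plus a constant
baseline. Its full width at half maximum, FWHM = 2√(2 ln 2) σ ≈ 2.3548 σ,
measures the metaphase spindle length.

**Anaphase.** After chromosomes start to separate, the profile develops one
tall central peak (the antiparallel overlap region) flanked by two lower
shoulders (regions of mostly parallel microtubules). The fitted model is a
sum of three Gaussians with the side peaks *constrained* to be equidistant
from the centre and identical in height and width — 7 free parameters
(A_c, x₀, σ_c, A_s, d, σ_s, b) instead of 10. Two derived quantities carry
the biology:

* overlap length `L = 2.3548 σ_c` (central FWHM), and
* total profile width `W = 2 d + 2.3548 σ_s` (side-peak separation plus one
  side FWHM), a measure of spindle length.

The constraint reflects the left–right symmetry of a bipolar spindle and
stabilizes the fit early in anaphase when the shoulders are barely
resolved. `fit_anaphase_profile()` reports a *reliability flag* for L:
relative SE(σ_c) < 50%, σ_c < d, and A_c > A_s. Early-anaphase profiles
routinely fail this flag — the central peak is then broad, weak and
entangled with the shoulders — which mirrors the fact that overlap lengths
can only be measured reliably a few minutes into anaphase. Time-course
consumers (`fit_overlap_decay()`) use only flagged-reliable points and
extrapolate the fitted mono-exponential back to early anaphase.

**DNA.** Two spatially displaced, otherwise identical Gaussians; the
distance between the means is the chromosome separation. When the fitted
separation is below one σ the two masses are not actually resolved: the
likelihood is nearly flat in *s*, so the fit is flagged `resolved = FALSE`
and the reported SE is floored at σ̂/2 rather than trusting the
curvature-based value.

## The synthetic forward model

`spindle_sim_config()` + `generate_spindle_movie()` /
`generate_spindle_kymograph()` simulate the study conditions with known
ground truth:

* **Geometry.** Poles 8 µm apart in metaphase, elongating linearly to a
  20 µm plateau over the first 5 min of anaphase, then constant — the
  elongation behaviour measured in RPE1 cells. Chromosome separation tracks
  pole elongation during that phase and then creeps at 0.3 µm/min, so
  separation and spindle length are strongly coupled during elongation.
* **Profile evolution.** After onset the central FWHM decays
  mono-exponentially from 6 µm towards 1.7 µm (τ_L = 2 min) and the side
  peaks sit so that W equals the current pole distance. Mono-exponential
  schedules were chosen because the decay-fit stage itself is
  mono-exponential; the generator and the analysis then share a model
  family, which is exactly what a parameter-recovery validation needs.
* **Mass conservation.** The axial profile is parameterized by a conserved
  integrated intensity and a *central mass fraction* rising from 0.40 to
  0.85 (τ = 3 min). Compaction (falling σ_c) plus mass transfer makes the
  central amplitude rise steeply — reproducing the observed intensity
  increase — while the noiseless, bleach-free movie conserves total
  intensity exactly, a property the tests assert.
* **Rendering.** 2-D frames are the axial profile times a transverse
  Gaussian envelope (σ = 2 µm crosslinker, 2.5 µm DNA; real transverse
  structure is not modelled), optionally rotated/offset to exercise the
  alignment stage, times a global photobleaching factor `e^{−kt}`, plus
  background and noise. Noise is additive Gaussian (SD expressed in units
  of the metaphase peak amplitude) or scaled Poisson (`counts = gain ×
  intensity`), the two models that bracket sCMOS camera behaviour. Camera
  gain and background level are free parameters; nothing in the analysis
  depends on their absolute values because profiles are
  background-subtracted and FRAP curves normalized.
* **Determinism.** One master seed; every entity (frame, curve, track)
  draws its own child seed derived from it, so outputs are bit-reproducible
  and ensembles are embarrassingly independent.

FRAP curves follow `I(t) = I₀ + I_a (1 − e^{−t/τ})` with
`I_a = m_f (1 − I₀)`, five pre-bleach frames, a bleach-frame drop to I₀,
and 2 s sampling over 180 s by default (30 frames/min over 3 min, the
standard acquisition). The recovery clock starts at the first post-bleach
frame; the generator and `fit_recovery()` share this convention, and the
bleach-frame sample only seeds the I₀ initial guess. A per-curve random
intensity scale (80–120) makes the normalization stage do real work.
`m_f > 1` is accepted but warned about as an unphysical overshoot. Comet
tracks move at constant velocity with Gaussian per-track speeds truncated
at zero and geometric (discrete-exponential) durations, the distribution
implied by a constant per-frame termination probability.

Defaults that the source measurements do not pin down numerically were set
once to field-typical values and not revisited: comet stage speeds fall
from 0.33 µm/s (metaphase) to 0.18 µm/s (telophase), matching typical
RPE1 microtubule growth speeds and the reported ~30% slowdown; the
intermediate PRC1 recovery fractions and the CLASP1 stage assignment
interpolate linearly between the published endpoints, with the slowest
CLASP1 time (2.9 s) assigned to telophase by analogy with the other two
proteins (`frap_stage_presets()` marks these rows `interpolated`).

## Pipeline stages and their numerical choices

**Alignment.** Each frame is translated and rotated so the annotated pole
midpoint sits at the image centre and the axis is horizontal. Resampling is
inverse-mapped bilinear interpolation; pixels whose source falls outside
the field are `NA` and excluded from every downstream mean, never filled.

**Kymograph extraction.** One row per frame, each the per-column mean over
an 8 µm band centred on the axis (0.3 µm for plus-end comet work). A band
wider than the image is clipped with a warning.

**Anaphase onset.** Per-frame DNA fits give a separation series; onset is
the first frame whose separation exceeds 20% of the metaphase pole distance
for ≥ 3 consecutive frames. Because a ramp crosses any threshold one or two
frames late, the separations of the first frames above threshold are
back-extrapolated linearly to zero separation (clamped to at most six
frames before the crossing). This lands within ±1 frame of the true start
on ramped separations and, unlike walking backwards frame by frame, is not
fooled by the spurious small separations that unresolved pre-onset profiles
produce under noise.

**Averaging.** Each cell's spatial axis is rescaled by (mean metaphase pole
distance / own metaphase distance) and linearly interpolated onto a common
grid; time is shifted so onsets coincide; per-bin mean, n and SEM are
accumulated. Averaging is permutation-invariant and `NA`-aware.

**Background and bleaching.** Background is the per-frame median of the
outermost 10% of kymograph columns (off-spindle). Bleaching correction
(optional) divides each row by `e^{−k̂t}` with k̂ from a log-linear fit to
total in-band intensity over time; because the generator conserves
intensity, k̂ estimates the true bleaching rate rather than absorbing
biological redistribution.

**Least squares.** All nonlinear fits run Levenberg–Marquardt
(`minpack.lm::nls.lm`) with *analytic* Jacobians generated by `deriv()`,
box bounds (amplitudes ≥ 0, widths within [half a pixel, profile span],
d ∈ (0, span/2], τ ∈ [frame interval, 10× window], I₀ ∈ [0, 1],
I_a ∈ [0, 1.5]), and tight tolerances — noiseless inputs are recovered to
machine precision, which the tests assert. Standard errors come from
σ̂²(JᵀJ)⁻¹; derived quantities (W, m_f, I_E, FWHM) get delta-method SEs
using the full covariance. Weights are inverse-variance whenever per-point
SEMs exist, else unweighted.

**Initialization and multi-start.** Gaussian seeds come from moments
(centroid, second moment); the anaphase side-peak offset is seeded from the
outermost *local* maxima after light smoothing — a plain windowed maximum
can land on the central peak's tail and trap the fit in a local minimum.
If the first solution fails to converge or leaves an RMS residual above 2%
of the profile range, five seeded perturbations of the initial guesses
(with the side-peak offset swept across its admissible range) are tried and
the lowest-deviance solution kept. The DNA fit similarly sweeps separation
starts whenever it lands in the unresolved regime, where the `s = 0`
boundary is an attractor. Degenerate anaphase solutions (vanishing side
peaks, or σ_c ≥ d) fall back to the single-Gaussian model with L marked
unreliable.

**FRAP windows.** A fitted τ larger than half the observation window is
flagged `window_limited` and its SE is doubled: with most of the plateau
unobserved the curvature-based SE is an honest underestimate. The slowest
published recovery (124 s against a 180 s window) triggers this path by
design.

**Stage classification.** Deterministic rules: separation < 1 µm is
metaphase; anaphase is split at thirds of the *elongation span* (plateau
minus metaphase pole distance; with the default 20 − 8 = 12 µm geometry the
cuts are 4 and 8 µm); telophase additionally requires a plateaued
separation and a compact dominant central peak (L < 2.5 µm, A_c/A_s > 3).
Thirds of the span rather than of the plateau distance itself were chosen
because chromosome separation on this geometry never reaches two thirds of
the full pole distance, which would make the late-anaphase label
unreachable. Contradictory evidence (e.g., metaphase-level separation with
a compact anaphase profile) returns `"unknown"` rather than a silent guess.

**Comet statistics.** Speed is endpoint displacement over elapsed time (a
track returning to its start has speed zero — deliberately not path
length); the per-stage summary reports the median with the SEM, plus a
median-absolute-deviation alternative. Manual trajectory polishing is
replaced by the explicit ≥ 3-frame filter; no gap-stitching is applied by
default.

## File formats

Movies are multi-page 32-bit TIFF with a JSON sidecar carrying pixel size,
frame interval, channel names, axis order, and an exactly invertible
power-of-two intensity scaling; reading without calibration is an error.
The TIFF container quantizes intensities onto its 32-bit grid, so a round
trip is exact only to ~5 × 10⁻¹⁰ of the dynamic range — metadata round
trips exactly. Trajectories are CSV (`track_id, frame, time_s, x_um`);
configurations are YAML written at 17 significant digits so they round-trip
doubles losslessly, with unknown keys rejected; results are JSON with a
provenance block (config hash, seed, package version).

## Validation scale and limitations

The shipped tests run the whole pipeline at desk scale: 31-frame,
2-channel, 140 × 320 px movies (0.1 µm pixels, 30 s frames), 17-cell
ensembles, FRAP ensembles of 10–18 curves at 2 s (or 0.5 s for fast
kinetics) sampling, and a few hundred comet tracks — sizes chosen so each
stage is exercised end-to-end while the full suite stays fast enough to run
on every change.

What passing these tests shows is that the *estimators are correct*: each
stage recovers the generator's parameters at the stated tolerances, agrees
with independent brute-force oracles, and respects the symmetry and
conservation invariants. What it cannot show is robustness to everything
real microscopy adds that the forward model omits: no optical PSF or
defocus, no z-structure (the three acquired planes are reduced before
analysis), no cell-to-cell variation in profile *shape* (only in scale,
onset and noise), no bright crosslinker streaks outside the midzone (on
real data these enter the fit residuals), no drift or annotation error in
the pole positions, and comet tracks that are ideal constant-velocity
segments rather than tracker output with splits and gaps. Results on real
data therefore depend on upstream quality — pole annotation, tracker
curation — in ways the synthetic validation deliberately leaves out of
scope.
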
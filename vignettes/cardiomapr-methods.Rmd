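---
title: "Optical-mapping metrics for hiPSC-CM monolayers: models, estimators, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical-mapping metrics for hiPSC-CM monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomapr)
```

# The measurement problem

Optical mapping images transmembrane voltage or intracellular Ca²⁺ across a
cardiomyocyte monolayer with a fluorescent indicator and a high-speed,
low-resolution camera (here a 100×100-pixel class sensor). The signal at
each pixel is an uncalibrated, noisy, drifting fluorescence trace; the
quantities of scientific interest are relative: action potential durations
(APD30/APD80), the maximal upstroke slope of the normalized signal, the
speed and uniformity of wavefront propagation, calcium-transient rise and
decay kinetics, and the spatial dispersion of these quantities across the
syncytium. This package implements that measurement chain end to end, plus
the adjacent assays a monolayer study typically pairs with it (qPCR
relative quantification, Z-line morphometry, group statistics).

No raw recordings accompany studies of this kind, so validation is by
construction: a synthetic generator produces movies from an analytic
per-pixel model with known ground truth, and the pipeline must recover that
truth. The test suite and `scripts/acceptance.R` are organized entirely
around such parameter-recovery checks.

# The synthetic monolayer model

`simulate_movie()` builds each pixel's trace as

```
F(t) = baseline + amplitude · template(t − t_act; pixel parameters) + drift(t) + noise
```

* **AP template** (`ap_template()`): piecewise linear — a linear upstroke
  of duration *u*, then two linear repolarization segments pinned so the
  envelope crosses 70% of peak exactly at `apd30` and 20% exactly at
  `apd80` after activation onset, then a linear tail to zero at
  `1.15·apd80`. The piecewise-linear form gives closed-form APD ground
  truth at any sampling rate.
* **Ca template** (`ca_template()`): linear rise over `time_to_peak`, then
  `exp(−t/decay_tau)`. Successive beats superpose additively, so at a
  1000 ms cycle with τ = 400 ms the diastolic fluorescence does not return
  to rest between beats — exactly the situation a real Rhod-2 recording
  presents — while the rest-referenced decay remains a single exponential
  (a sum of same-τ exponentials is one exponential).
* **Wave geometry**: activation time = stimulus time + distance from the
  stimulated edge / `planar_wave_speed` (line electrode along one edge), or
  radial distance for a point source. Ground-truth conduction velocity is
  therefore exactly the configured speed.
* **Heterogeneity**: a lognormal multiplicative factor on the per-pixel
  upstroke duration (and optionally on the duration parameters). Since the
  per-pixel upstroke velocity is `1/u`, a lognormal sigma of
  `sqrt(log(1 + RSD²))` induces a chosen velocity RSD
  (`upstroke_sigma_for_rsd()`).
* **Drift**: `b0 + b1·t + b2·exp(−t/τ_b)` counts, spanning the linear and
  exponential photobleaching shapes the preprocessor must remove.
* **Noise**: additive white Gaussian, parameterized as a fraction of the
  signal amplitude.

## Default acquisition and kinetic parameters

| parameter | default | why |
|---|---|---|
| frame interval | 2 ms (500 Hz) | typical for 100×100 CMOS mapping cameras |
| pixel pitch | 0.1 mm | ~1 cm field of view over 100 pixels |
| planar wave speed | 0.2 mm/ms (20 cm/s) | hiPSC-CM monolayer CV range |
| upstroke duration | 10 ms | hiPSC-CM optical upstrokes are slow (≈10–30 ms); also the shortest rise a 2 ms central-difference derivative can represent without saturating at 1/(2·dt) |
| baseline / amplitude | 1000 / 2000 counts | mid-range of a 16-bit camera |
| pacing | 1000 ms cycle, 3 beats, first stimulus at 100 ms | the lead-in before the first beat samples the true diastolic resting level |

All are configurable; the acceptance runs use 100×100 grids at these
defaults (40×40 for the 16-movie group contrast, 30×30 for the 30 s
spontaneous recording — sizes chosen so each quantity is still estimated
from thousands of pixels or tens of beats).

What the generator does **not** emulate: electrotonic coupling (each pixel
is an independent copy of the template), motion artifact (the study class
uses blebbistatin), dye photophysics, stimulus artifacts, reentry. Passing
recovery tests on these movies therefore validates the *estimators* —
normalization, crossing detection, plane fitting, decay fitting — not the
pipeline's behavior under motion or arrhythmia.

# Preprocessing

**Drift removal** (`remove_baseline()`) fits a slow model (quadratic
polynomial by default, or linear + exponential with the time constant
profiled on the pooled diastolic trace) to diastolic samples only and
subtracts the mean-centered fit, leaving beat morphology untouched. The
diastole set is channel-aware. For voltage, action potentials repolarize
fully, so every sample where the smoothed field-mean trace sits within 2%
of its per-beat range above the per-beat minimum is diastole; the selection
is eroded by two frames so samples bordering the upstroke foot or the
repolarization tail never enter the fit (this also makes zero-drift input
an exact fixed point). For calcium the inter-beat diastole is elevated by
the undecayed tail, and only the pre-stimulus segments of the second and
later beats — which sit at the converged steady-state level — are used,
with the polynomial degree capped at one less than the number of such
segments.

**Masking** (`mask_pixels()`): a pixel is valid when its beat-averaged
signal amplitude divided by the SD of its high-frequency residual (trace
minus a 5-frame moving average) reaches the threshold (default 3).
Noiseless tissue is always valid; flat pixels never are; raising the
threshold can only remove pixels.

**Normalization** (`normalize_beats()`): per pixel per beat,
`(F − F_min)/(F_max − F_min)` with `F_min` the mean of the pre-stimulus
diastolic samples (stimulus-artifact guard excluded) and `F_max` the
in-window maximum — so a noiseless beat has diastole exactly 0 and peak
exactly 1, and the operation is idempotent. The resting level of the
lead-in before the first stimulus is carried along in normalized units for
the calcium decay fit. Beats are analyzed separately and **metrics** are
averaged per pixel (robust to beat-to-beat jitter); the first paced beat is
discarded as a capture transient.

**Spatial smoothing** (`spatial_filter()`) is masked-normalized Gaussian
filtering, available but **off by default** in the pipelines: averaging
neighboring pixels shrinks exactly the spatial-heterogeneity (RSD) metrics
the study cares about.

# AP metric estimators

The per-trace estimators were chosen so that their errors stay well below
the group differences of interest at 5% amplitude noise; each choice is a
response to a specific failure mode of the naive estimator.

* **Activation** = time of maximum first derivative (central differences),
  refined to the midpoint crossing of the fitted upstroke line — for a
  locally linear upstroke this is the center of the maximum-derivative
  ramp, located independently of the sampling phase (the three-point
  quadratic refinement of the discrete argmax is the fallback). Phase
  independence is what makes pipeline-measured activation maps smooth
  enough for exact planar-wave CV recovery.
* **Upstroke velocity** = slope of the line fitted through the samples
  whose derivative exceeds half its maximum. The raw maximum central
  difference is a maximum over noisy quantities (positively biased, more
  so for slow pixels, which compresses the velocity RSD) and saturates at
  `1/(2·dt)` for fast upstrokes; the fitted slope is unbiased for a
  locally linear rise and reproduces `1/u` exactly on clean data.
* **Amplitude reference**: the intersection of the upstroke line with a
  line fitted to early repolarization. The raw in-window maximum is
  inflated by roughly 2 noise SDs (a maximum over many near-peak samples),
  and an amplitude bias ε displaces an APD crossing by
  `ε·(1 − level)/|repolarization slope|` — tens of ms for APD30 at 5%
  noise. The line-intersection estimate is unbiased to first order.
* **APD crossings**: localized as a sustained (two-sample) sub-threshold
  crossing of a 9-frame moving average, then refined by a least-squares
  line on the raw samples just *past* the crossing; the one-sided window
  keeps the fit on a single repolarization segment, so the refinement is
  unbiased even when the crossing coincides with a change of
  repolarization slope (as APD30 does for this template family).
* **APD reference**: by default APDs are referenced to the extrapolated
  upstroke foot (activation onset), matching how APD ground truth is
  defined from the template; `apd_ref = "dfdt"` switches to the
  maximum-derivative time (the two differ by at most the upstroke
  duration, and the choice is reported by the functions' documentation
  rather than buried in the number).

With these choices a noiseless movie is recovered to sub-frame precision
at every pixel, and at 5% noise the monolayer means stay within ~2% of
truth (the per-pixel scatter is unbiased and averages out across 10⁴
pixels).

# Conduction

`local_velocity()` fits `T(x, y) = a + bx + cy` over a `(2r+1)²`
neighborhood (default r = 2) of each pixel of the beat-averaged activation
map, in mm; the local velocity is `(b, c)/(b² + c²)` and the speed
`1/√(b² + c²)`. Pixels are invalidated when under half the neighborhood is
populated (mask edges), when the RMS plane residual exceeds 2 ms, or when
the gradient is degenerate. A first-order fit is used deliberately: on
100×100 grids, quadratic terms add variance without detectably reducing
bias at this neighborhood size. Mean CV converts 1 mm/ms = 100 cm/s;
conduction heterogeneity is the RSD of valid local speeds, mirroring the
upstroke heterogeneity metric (the field reports "conduction
heterogeneity" without a standard formula; RSD is the symmetric,
least-surprising choice and is easy to replace). On noiseless planar ramps
the fit recovers speed and direction to numerical precision at any wave
angle — this is the conduction oracle in the acceptance suite.

# Calcium kinetics

**Time to peak** runs from the onset foot — the upward crossing of 10% of
amplitude extrapolated along the fitted rise line to baseline — to the
apex located as the intersection of the rise line and an early-decay line.
Both constructions are exact for the template and robust to noise on the
sharp apex; a derivative-maximum onset is deliberately avoided because Ca
upstrokes are slow and their derivative maxima poorly localized.

**Decay rate** is fitted on the segment between 90% and 30% of the
rest-referenced amplitude. The default estimator fits
`a·exp(−kt) + c` with the offset free, profiling k (for fixed k the model
is linear in a and c), in original units where the noise is homoscedastic.
The classical log-linear fit of `log(F − rest)` is available as
`method = "loglinear"` and agrees within 2% on clean monoexponential
input, but it is exquisitely sensitive to small errors in the assumed
resting level near the lower bound — and at a 1000 ms cycle with
τ = 400 ms the resting level must itself be estimated from an incompletely
decayed recording. A rate pinned at the profiling floor (no resolvable
exponential curvature, e.g. a voltage trace passed by mistake) is flagged
invalid, as are fits with R² < 0.8. Rates are reported in 1/s (reciprocal
τ); the estimator is named in the documentation because "decay rate" has
no unique field-wide definition.

# qPCR quantification

`nrq()` implements the efficiency-corrected multi-reference-gene model:
technical replicates collapse to mean Cq (replicate SD > 0.5 cycles is
flagged); `RQ = E^(Cq_cal − Cq)` per gene (default E = 2, overridable per
gene); the per-sample normalization factor is the geometric mean of the
reference-gene RQs; group means and standard errors are computed on
log(NRQ) across biological samples and back-transformed by the delta
method; finally each gene is rescaled so the calibrator-group mean is 1
(rescaling after averaging — the alternative order changes nothing in the
noise-free case and the choice is recorded here). A sample-wide Cq shift
(loading) cancels exactly, and noise-free synthetic tables are recovered
to machine precision for any E in (1, 2].

# Z-line morphometry

The study protocol this emulates had a blinded human measure
α-actinin-positive lines inside script-chosen 20 µm ROIs; an automated,
deterministic measurement replaces the human so the procedure is testable.
`select_rois()` draws uniformly random non-overlapping square ROIs
(seeded; an unlucky early placement triggers a layout restart).
`detect_zlines()` applies hysteresis thresholding in robust-SD units above
the background median (high 6, low 2.5 — pure-noise ROIs yield nothing),
Guo–Hall thinning (Zhang–Suen erodes 2-px diagonal staircases and was
rejected), reduction to a minimal 8-chain, pruning of ≤4-px spurs,
splitting at remaining branch points, and corner-corrected chain-code
length (0.980·straight + 1.406·diagonal − 0.091·corners, plus a 1-px
endpoint compensation for thinning retreat). Segments touching the ROI
border are excluded as censored — note this slightly biases pooled means
downward for populations of long segments. Accuracy on synthetic strokes:
mean error ≈ 0.2 px across orientations, worst case ≈ 3 px at unlucky
angle/noise combinations; pooled group means recover truth within 2–3%.

# Statistics

`welch_t()`, `holm_bonferroni()` and `ci95()` wrap the standard R
implementations (`t.test`, `p.adjust`, `qt`), with the test suite holding
them to independent from-scratch formula oracles at 10⁻¹⁰.
`compare_groups()` runs all pairwise Welch tests within each family and
Holm-adjusts within the family; a family defaults to one metric (at one
pacing rate, if such a column is supplied) — the narrowest defensible
reading of family-wise correction, and overridable via `family_keys`.
Two-tailed α = 0.05 throughout.

# Known limitations

* The generator's pixels are kinetically independent; there is no
  electrotonic smoothing, so recovered heterogeneity on real data will be
  lower than the cellular truth in a way these tests cannot quantify.
* APD estimates carry a small (−1 to −3 ms) systematic at 5% noise from
  sustained-crossing localization; this is well inside the 3% acceptance
  envelope but not zero.
* Decay rates at cycle lengths short relative to τ depend on the
  offset-profiled fit; with < 5 samples between the 90% and 30% levels the
  pixel is invalidated rather than extrapolated.
* Z-line border censoring biases pooled means of long-segment populations
  downward by a few percent.
* The CLI-free design is intentional: the numbered scripts under
  `analysis/` are the workflow surface, and all computation lives in
  package functions.
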
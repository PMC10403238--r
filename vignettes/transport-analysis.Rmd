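---
title: "Characterizing anomalous particle transport with sptddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing anomalous particle transport with sptddm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptddm)
```

## The problem

Micron-scale particles moving through crowded, active soft matter — the
cytoskeleton being the canonical example — rarely show simple Brownian
motion. Their mean-squared displacement (MSD) follows
`MSD(dt) ~ dt^alpha` with `alpha < 1` (subdiffusion, from caging in the
surrounding mesh) or `alpha > 1` (superdiffusion, from motor-driven
advection), often with crossovers between regimes at characteristic lag
times. Their displacement distributions (van Hove functions) deviate from
Gaussianity, growing exponential tails when transport is heterogeneous
(hopping between cages) and asymmetry when there is a preferred direction
of motion. `sptddm` implements a complete characterization pipeline for
such systems from two independent observables:

* **Real space (SPT)** — from particle trajectories: the ensemble
  time-averaged MSD with multi-phasic regime detection, and per-lag van
  Hove distributions with width, asymmetry and mixture statistics.
* **Reciprocal space (DDM)** — from raw image stacks, with no tracking at
  all: the radially averaged image structure function `D(q, dt)`, its
  per-wave-vector decay time `tau(q)` and stretching exponent
  `gamma(q)`, and the scaling `tau(q) ~ q^-beta`.

The two observables probe different spatiotemporal windows (SPT resolves
sub-pixel displacements over short times; DDM reaches larger length and
time scales without localization), so agreement between them is a strong
consistency check, and disagreement is itself informative.

## Conventions

Throughout the package the MSD uses the half-sum convention

```
MSD(dt) = 0.5 * ( <dx(dt)^2> + <dy(dt)^2> )
```

so that normal diffusion with diffusivity `D` gives `MSD = 2 D dt` and a
single particle at constant speed `v` gives `MSD = 0.5 v^2 dt^2`. The
generalized coefficient `K` used by the generators is the prefactor of
this convention (`K = 2D` for Brownian motion). For Gaussian
displacements the two observables are linked through the intermediate
scattering function `f(q, dt) = exp(-q^2 MSD(dt) / 2)`, which is what
makes `alpha = 2 / beta` the correct translation between the SPT and DDM
exponents.

## The synthetic-data module

No reference microscopy data ship with the package; instead, the
generators produce trajectories and rendered image stacks whose transport
parameters are known exactly, and every analysis stage is validated
against them.

* `gen_fbm_tracks()` — fractional Brownian motion with *exact*
  fractional-Gaussian-noise increment covariance, synthesized by
  circulant embedding (Davies–Harte). An exact method matters here:
  approximate integrators bias the recovered `alpha`, which is the main
  quantity the tests assert on. Per-axis displacement variance is
  `K (k dt)^alpha` by construction at every lag.
* `gen_ballistic_tracks()` — quenched disorder: each particle receives a
  constant velocity (truncated-normal magnitude, or uniform bounds;
  wrapped-normal direction around a drift axis, isotropic by default).
  A constant per-particle velocity is the simplest model that produces
  both the ballistic MSD signature and non-zero van Hove modes; the true
  displacement distribution of an active network is not known, and this
  stand-in should be read as such.
* `gen_caged_hopping_tracks()` — per-axis Ornstein–Uhlenbeck confinement
  with stationary standard deviation `cage_size`, plus Poisson-timed
  cage-center hops with exponential lengths. The model has no free
  relaxation-time parameter: `K` doubles as the short-time MSD prefactor
  inside the cage, fixing `tau_r = 2 cage_size^2 / K`. The hop-free MSD
  plateaus at `2 cage_size^2`.
* `gen_multimode_tracks()` — the sum of an fBm component and a ballistic
  component whose speed is chosen so the two analytic MSD terms are equal
  exactly at `crossover_time`. The analytic curve
  `K t^alpha + 0.5 v^2 t^2` is the ground truth the detectors are tested
  against; its MSD/dt minimum sits at
  `(1 - alpha)^(1/(2 - alpha)) * crossover_time` and is recorded in the
  output metadata. Note that near the crossover the local slope of the
  sum is genuinely below 2, so "recovering alpha2" means matching a
  power-law fit of the analytic curve over the *same* lag window, not
  the asymptotic exponent.
* `render_image_stack()` — Gaussian point-spread rendering
  (`psf_sigma = 0.5` um by default, approximating a 1 um emitter) on a
  uniform background with Poisson noise on signal + background
  (sCMOS-like counting statistics). Default geometry emulates light-sheet
  acquisition at 10 frames/s and ~0.2 um/px. Particles that wander out of
  the field of view stay in the track table but are not rendered, which
  mirrors real tracking truncation without touching the MSD code.

What the generators deliberately do **not** emulate: filament-level
network mechanics, hydrodynamic coupling, photobleaching,
depth-dependent illumination, or localization error in the track tables.
Passing tests therefore demonstrate that the *analysis* is correct and
self-consistent, not that any particular biological system behaves like
the generators.

## Real-space analysis choices

**Averaging.** `compute_msd()` pools all displacement pairs of all
particles (time average within tracks, then across the ensemble, weighted
by pair count). Pooled weighting is the statistically efficient choice
when track lengths vary; per-trajectory-first averaging is the main
alternative and would weight short noisy tracks more heavily. Lags
supported by fewer than `min_pairs = 50` pairs are dropped, and
`read_tracks()` drops tracks shorter than `min_track_length = 10` frames
(both configurable, both logged).

**Regime boundaries.** `detect_t1()` implements an expanding-window
criterion: the end of the initial power-law regime is the largest window
`[first lag, t]` over which a log-log regression keeps `R^2 > 0.99`.
Windows smaller than 5 lags are not considered (R-squared on fewer points
is uninformative), and the criterion uses all lags in the window.
`detect_t2()` finds the first strict local minimum of smoothed `MSD/dt`
— the point where the effective exponent crosses 1 from below. Two
numerical guards are layered on the bare rule: a 5-point centered moving
average (raw `MSD/dt` at long lags is dominated by low statistics), and a
prominence requirement (default 0.1 log units of drop before and rise
after the minimum), because on a genuinely monophasic curve statistical
ripple always produces *some* strict local minimum. Ties break toward
the smaller lag: the earliest transition is the conservative choice. A
curve whose `MSD/dt` rises from the very first lag has no subdiffusive
regime at all; the first lag is returned flagged degenerate.

**Regime fits.** `fit_regimes()` fits unweighted least squares on
(log lag, log MSD) per regime — matching the log-log space in which the
`R^2` criterion is defined — after subsampling the lag grid to at most 30
log-spaced points per decade so that the dense, highly correlated
long-lag points do not dominate. Boundary lags belong to both adjacent
regimes. An intermediate regime is fitted only when its window holds at
least 5 subsampled lags; regimes with fewer than 3 lags are reported
absent, never extrapolated. The fit cap (largest lag entering any fit)
defaults to the end of the curve and should be lowered for
low-statistics data.

**Van Hove distributions.** `compute_van_hove()` histograms displacements
on uniform bins (default width 0.05 um, about the localization-precision
scale of typical SPT data) with one bin centered on zero and symmetric
support covering the 99.9th percentile of |displacement|, normalized to
unit area. The pooled axis concatenates x- and y-displacements; per-axis
distributions are available for anisotropy analysis.

**Mode and edges.** The mode `d_peak` is found by parabolic
interpolation around the maximal bin, fitted by least squares over a
window that grows from the minimal 3 points until the density drop
across it exceeds five times the Poisson noise scale of one bin. The
adaptive window matters for broad, finely binned distributions: there the
argmax bin alone wanders several bins under counting noise, and since
both half-widths are measured from the mode, that error would enter the
asymmetry statistic doubled. For noise-free input the window stays at 3
points (the classical parabola), keeping the estimator deterministic
with no kernel bandwidth as a hidden parameter. Half-maximum crossings
are located by linear interpolation on each side. The *leading* edge is the side whose
displacements share the sign of the mode (the side moving with the bulk);
the opposite side trails. When the mode is within one bin of zero the
distribution is treated as symmetric and leading defaults to the positive
side, flagged in the output. The asymmetry statistic is the fractional
excess of the trailing half-width over the leading one.

**Width scaling.** For Gaussian transport `FWHM^2` scales like the MSD,
so `fit_fwhm_scaling()` regresses `log FWHM^2` on `log lag` and reports
the slope as `alpha` directly. (Fitting `FWHM ~ dt^(alpha/2)` would give
the identical exponent; the squared form is used because width-squared is
the variance-like quantity.) The default regime split at 1 s is
inclusive on both sides — the boundary lag is cheap to share and the
exponents are insensitive to its assignment.

**Mixture fits.** `fit_gauss_exp()` fits
`A exp(-d^2 / 2 sigma^2) + B exp(-|d| / lambda)` with both terms sharing
a common center (the mode; zero emerges automatically for symmetric
data). One-sided fits restrict the data to the leading or trailing side
of the mode but keep the full functional form, so the amplitude fractions
`a = A/(A+B)` and `b = B/(A+B)` are comparable across sides. The fit is
bounded nonlinear least squares with a small multi-start grid over
`sigma` and `lambda` starting values, which reliably avoids the local
minimum where the Gaussian term absorbs the exponential tail. Amplitude
fractions are identifiable in practice for `lambda/sigma >= 1.5` at
10^5 displacements; below that the two shapes become degenerate and `a`,
`b` should be read with caution.

## Reciprocal-space analysis choices

`image_structure_function()` computes
`D(q, dt) = < |FFT2(I(t + dt) - I(t))|^2 >` over about 20 log-spaced lags
per decade, averaging up to 300 frame pairs per lag with a deterministic
(evenly strided, never random) subsample, then radially averages over
annuli one FFT bin wide with the annulus mean |q| as the bin center. The
zero-frequency pixel is excluded. No window function is applied by
default; windowing changes the absolute amplitudes `A(q)`/`B(q)` but not
the decay times, and the rendered synthetic stacks have no edge
discontinuities. Per-pixel normalization preserves total power
(a Parseval identity checked in the tests).

`fit_ddm_matrix()` fits
`D(q, dt) = A(q) (1 - exp(-(dt/tau)^gamma)) + B(q)` per q bin by bounded
Levenberg–Marquardt out to a 100 s lag cap, with initial values read off
the data (`B0` = min, `A0` = max − min, `tau0` at the 1 − 1/e crossing,
`gamma0 = 1`) and `gamma` bounded to [0.2, 3] — wide enough to span
confined (`gamma < 1`) through compressed, advective (`gamma > 1`)
decays with margin. The background `B(q)` is fitted freely rather than
pinned to a high-q estimate. Non-converged bins are flagged and excluded
downstream, with the count reported.

`fit_tau_powerlaw()` regresses `log tau` on `log q` over converged bins
in the fit band (default 1–4 um^-1, configurable; for strongly advective
data a 1.5 um^-1 lower edge often isolates the single-power-law region)
and reports `beta` with `alpha_ddm = 2/beta`. Two diagnostic flags guard
the band edges: a low-q plateau flag (local slope magnitude of the three
smallest-q bins below 0.5 — the signature of the finite field of view
and finite lag range) and a high-q uptick flag (`tau` rising with `q` at
the top of the band — the signature of the optical resolution limit).
`average_gamma()` reports the q-averaged stretching exponent with its
standard error and a q-insensitivity diagnostic; a `gamma(q)` with a
significant slope in `q` undermines the interpretation of a single
`beta`.

## The detectability timescale

Advection at network speed `v` becomes visible in a trajectory only once
it moves a particle beyond the minimum resolvable displacement, i.e. at
lag times beyond `dt_a = resolution / v`. `compute_detectability_timescale()`
implements this arithmetic; with a 100 nm resolution scale and speeds of
2.2–85 nm/s it brackets roughly 1–50 s, which is where crossover times
out of caged subdiffusion should (and in the multimode synthetics do)
fall.

## Orchestration

`run_full_analysis()` drives all stages over a list of conditions (each
with a track table and/or an image stack, as objects or file paths) from
a single config list and joins the per-method exponents, regime
boundaries and stretching exponent into one summary table. Partial
inputs produce partial rows — missing metrics are `NA`, never zero and
never silently dropped — and a failing stage is recorded in the `notes`
attribute while the remaining stages still run. Uncertainties are fit
standard errors for the exponents and the standard error over q for
`gamma`. A worked end-to-end example:

```{r pipeline, eval = FALSE}
cfg <- sim_config(n_particles = 150, n_frames = 1200, seed = 7)
tracks <- gen_multimode_tracks(cfg,
  motion_model("multimode", alpha = 0.35,
               generalized_coefficient = 0.02, crossover_time = 5))
summary <- run_full_analysis(list(
  conditions = list(list(label = "active-like", phi_A = 0.5, tracks = tracks)),
  params = list(msd = list(max_lag = 60))))
print(summary)
```

## Problem sizes and numerical notes

The validation suite runs at deliberately desk-scale sizes chosen so the
statistical tolerances hold with margin: 200 tracks of 2000 frames for
exponent recovery (`alpha` within 0.05), 150 particles in 800 frames of
256 x 256 px for the rendered DDM limits (`beta` within 0.15, `gamma`
within 0.1), and 10^5 displacements for mixture identifiability (`a`
within 0.05). These sizes are comparable to a single experimental
acquisition and keep every stage within a few minutes on one CPU; the
statistical error of all recovered exponents scales as expected with
ensemble size, so larger runs only tighten the tolerances.

Degenerate inputs are handled explicitly rather than numerically:
static tracks give exactly zero MSD and a single occupied histogram bin;
a zero generalized coefficient produces exactly constant positions;
identical frames give an identically zero structure function; curves
with too few lags, regimes with too few points, and under-resolved
histogram tails all raise descriptive errors instead of extrapolating.

## Known limitations

* Trajectories carry no localization error model; real SPT data have a
  noise floor that biases short-lag MSDs upward.
* Drift is a generator feature only; the analysis side deliberately does
  not subtract drift (in active systems the long-time directed motion
  *is* the signal, and inactive controls are the proper null).
* The van Hove mixture fit assumes a common center for both terms; for
  strongly advective data whose Gaussian and exponential populations
  move at different rates this is an approximation, and the one-sided
  fits are the more robust readout.
* DDM assumes uniform frame spacing and radially isotropic dynamics;
  direction-resolved structure functions are out of scope.
* Per-trajectory heterogeneity classification and formal non-Gaussianity
  parameters are not computed.
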
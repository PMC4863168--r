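---
title: "Classifying intracellular motion from single-particle tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying intracellular motion from single-particle tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(sptmotion)
library(dplyr)
```

## The problem

Vesicles that carry nucleic-acid cargo through the cytoplasm — endosomes
containing lipoplexes, for example — move by two qualitatively different
mechanisms. Thermal agitation produces Brownian diffusion; molecular motors
walking along microtubules produce directed ("flow") transport, typically as
*stop-and-go* motion in which directed runs alternate with diffusive pauses.
Which mechanism dominates has biological consequences: microtubule transport
feeds the endo-lysosomal degradation pathway, while freely diffusing
vesicles tend to avoid it. `sptmotion` takes 2D trajectories from
single-particle tracking (positions in µm, typically 1 frame/s for 2–5
minutes, i.e. 120–300 frames) and answers, per track and per track segment,
"diffusion or flow?", together with the transport parameters `D` and `v`.

Detection and linking of spots are upstream concerns (e.g. TrackMate);
`sptmotion` starts from the exported track table.

## Global analysis: the MSD and its two models

The time-averaged mean square displacement of a track at lag $\tau$ is the
average of squared displacements over all ordered frame pairs separated by
$\tau$ (overlapping pairs, the standard estimator). Long lags average few
pairs and are noisy, so lags are capped at 10% of the track time — the
common single-particle-tracking criterion, exposed as `max_lag_fraction`.

Two nested models are fitted by nonnegative least squares:

* Brownian: $\mathrm{MSD}(\tau) = 4D\tau + \varepsilon$
* Flow: $\mathrm{MSD}(\tau) = 4D\tau + (v\tau)^2 + \varepsilon$

`D` (µm²/s) is the diffusion coefficient, `v` (reported in µm/min, the
conventional unit for intracellular transport; internal computation is in
µm and s) the drift speed, and $\varepsilon$ (µm²) a positive offset equal
to four times the localization-error variance. All three parameters are
physically nonnegative, which is why the fit is constrained rather than an
ordinary `lm()`: the flow model is linear in $(D, v^2, \varepsilon)$, so
the constrained problem remains a nonnegative least-squares problem.

`select_model()` compares the pair with an F-test on the extra quadratic
term (default level 0.05, configurable; numerically exact linear fits
short-circuit to Brownian by parsimony). A caveat worth stating plainly:
successive MSD values share frame pairs and are strongly correlated, so the
nominal F-test level is optimistic and pure Brownian tracks are flagged as
"flow" far more often than 5% of the time. This is intrinsic to MSD-only
classification — it is exactly why the pipeline does not stop here but adds
an independent shape statistic.

```{r msd-demo}
trk <- simulate_brownian(D = 1e-3, n_frames = 300, seed = 1, noise_sd = 0.02)
fit <- select_model(compute_msd(trk))
glance(fit)
```

## Shape analysis: gyration tensor and asphericity

The gyration tensor $T_{ij} = \langle x_i x_j\rangle - \langle
x_i\rangle\langle x_j\rangle$ summarises where a track has been. Its
eigenvalues $\lambda_1 \ge \lambda_2$ give the asphericity

$$\alpha = \frac{(\lambda_1-\lambda_2)^2}{(\lambda_1+\lambda_2)^2},$$

a dimensionless number in $[0,1]$: 0 for isotropic (confined) exploration,
1 for motion along a line. It is invariant under translation, rotation and
uniform scaling, and — unlike the MSD fit — does not require choosing a
noise model.

Two ensemble estimators exist and differ materially for random walks.
Averaging the per-track ratios gives $\approx 0.40$; taking the ratio of
ensemble means, $\overline{(\lambda_1-\lambda_2)^2} \big/
\overline{(\lambda_1+\lambda_2)^2}$, converges to the closed form
$2(d+2)/(5d+4) = 4/7 \approx 0.571$ in 2D. `ensemble_asphericity()`
defaults to the ratio-of-means estimator because its Brownian reference
value is the one theory supplies; the per-track variant is available via
`estimator = "mean_of_ratios"`, and single-track values (used by the
segmentation) are always per-track ratios.

```{r alpha-demo}
ens <- simulate_ensemble(motion_domain("brownian", 100, D = 1e-3),
                         n_tracks = 2000, seed = 17)
ensemble_asphericity(ens)   # ~ 4/7
```

## Calibrating the asphericity threshold

How often does a *purely Brownian* track look directed? `calibrate_tail_probability()`
simulates ensembles of Brownian walks at each track length and estimates
$P(\alpha_{sp} \ge \alpha_{thr})$ empirically. Because $\alpha$ is scale
invariant, the simulation needs no diffusion coefficient. At the default
threshold $\alpha_{thr} = 0.8$ the tail probability lies between roughly 3%
and 8% over lengths of 10–300 frames (largest for the shortest tracks):
calling a Brownian stretch "flow" at this threshold is a few-percent
false-positive decision, which is what makes 0.8 a sensible default.

Distributions are stored as histograms of bin width 0.01, so the tail
integral is a bin sum and thresholds aligned to bin edges reproduce direct
counting exactly. Simulation is chunked (`chunk_size`), so the 10⁵-track
calibrations used for tight confidence bounds stream rather than
materialise.

```{r calib-demo}
cal <- calibrate_tail_probability(c(10, 30, 100, 300), n_sims = 2000, seed = 1)
tidy(cal)
```

## Local analysis: segmentation into motion domains

Whole-track statistics blur stop-and-go motion, so the classifier works on
short windows:

1. **Partition** each track into consecutive segments of `m = 3` frames
   (a remainder shorter than `m` is appended to the last segment so labels
   tile the track).
2. **Average speeds**: per segment, the mean of the per-frame finite
   differences gives speed components $v_x, v_y$.
3. **Ensemble thresholds**: $v^{thr}_{x,y}$ are 70% of the mean absolute
   segment speed components over *all* tracks being analysed. Thresholds
   are an ensemble property: the same track can be labelled differently in
   a different ensemble, so outputs carry the thresholds used. A segment is
   "above threshold" when $|v_x| \ge v^{thr}_x$ **or** $|v_y| \ge
   v^{thr}_y$ (the OR rule keeps axis-aligned drifts; AND is available).
4. **Classify sequences**: maximal runs of consecutive above-threshold
   segments are candidate flow domains. A run of two or more segments is
   labelled flow when its local asphericity $\alpha_L$ — computed on the
   run's own positions (at least 6 of them) — exceeds $\alpha_{thr} = 0.8$.
   Everything else is diffusion; adjacent same-label domains merge, and a
   degenerate (zero-extent) run falls back to diffusion.

The speed gate alone is weak — by construction roughly half of Brownian
segments exceed 70% of the mean — so the asphericity gate carries the
specificity, and the flow-labelled fraction of a purely Brownian ensemble
lands at the calibrated few-percent false-positive level. Two guarantees
hold on every output: each frame receives exactly one label, and no flow
domain is shorter than $2m$ frames.

```{r seg-demo}
dom <- bind_rows(
  motion_domain("brownian", 60, D = 3.7e-4),
  motion_domain("flow", 60, D = 3.7e-4, v = 2, heading = 0.4),
  motion_domain("brownian", 60, D = 3.7e-4)
)
ens <- simulate_ensemble(dom, n_tracks = 12, seed = 8, noise_sd = 0.02)
seg <- segment_tracks(ens)
population_fractions(seg)
```

`population_fractions()` reports both a time weighting (fraction of tracked
frames per motion kind) and a track weighting (fraction of tracks whose
dominant-by-time kind is each kind, ties to diffusion), because published
"population" bar charts rarely state which of the two they use; reporting
both makes the choice explicit.

## The synthetic-trajectory generator

No public raw movies accompany this kind of experiment, so the package
carries its own ground-truth generator. `simulate_stop_and_go()` builds
tracks from a table of motion domains: Brownian increments are Gaussian
with per-axis variance $2D\,dt$; flow domains superpose a constant drift
$v\,dt$ along a heading on top of the same Brownian jitter (directed
transport does not switch diffusion off). Localization error is Gaussian
noise added to the *stored* positions only — it does not propagate into the
path, which is precisely what makes $\varepsilon$ a constant offset in the
MSD rather than extra diffusion.

Defaults mirror the experimental regime the package targets: 1 frame/s,
120–300-frame tracks, $D \sim 10^{-4}\!-\!10^{-3}$ µm²/s, $v \sim
0.3\!-\!0.45$ µm/min. The localization error of the instrument is not
something simulation can derive; the default `noise_sd = 0.02` µm (a
typical confocal spot-fitting precision, giving $\varepsilon = 4\cdot
0.02^2 = 1.6\times10^{-3}$ µm²) is a synthetic convention and should be set
to the measured precision when one exists. Headings are fixed within a flow
domain (transport along one filament); `heading_shuffle` rotates each
track's headings by one random angle so ensembles do not share a direction.
Per-track seeds derive deterministically from the master seed (`seed + i`),
so ensembles are reproducible and individual tracks can be regenerated in
isolation.

What the generator does **not** emulate: confined or anomalous diffusion
(actin corralling), 3D motion projected to 2D, track-length bias from
detection failures, or gap-closing artefacts. Passing tests therefore
demonstrate correctness of the estimators and the classifier under the
stated motion model, not robustness to every pathology of live-cell data.

At physiological transport speeds the classification problem is genuinely
hard: a
drift of 0.45 µm/min moves a particle 7.5 nm per second while a single
diffusive step at $D = 3.7\times10^{-4}$ µm²/s has a standard deviation of
27 nm per axis. Frame-level agreement with ground truth on stop-and-go
tracks is therefore modest at the slowest drifts and rises steeply with
drift speed; the recorded sweep
(`tests/testthat/fixtures/segmentation-sweep.tsv`) pins the expected levels
(≈0.68 at 0.45 µm/min up to ≈0.97 at 8 µm/min) and the test suite holds
future changes to at least those.

## Colocalization

Two standard read-outs quantify whether the tracked cargo sits inside
marker-positive compartments. Pixel-based: `manders_m1()` computes
$M_1 = $ (above-threshold red intensity inside the green mask) / (total
above-threshold red intensity), with an optional Costes-style automatic
threshold (`costes_threshold()`: lower the candidate threshold until the
below-threshold pixels show no positive red–green correlation). Object-based:
`object_colocalization()` counts red centroids within `max_dist` of a green
centroid; the default 0.5 µm is a diffraction-scale convention, not a
measured value. Results aggregate as mean ± s.d. over images via
`summarise_colocalization()`.

## Numerical and design choices

* **Nonnegative least squares** (`pracma::lsqnonneg`) enforces $D, v^2,
  \varepsilon \ge 0$; degenerate all-zero MSD curves return zero parameters
  with a `degenerate` flag instead of failing.
* **Eigenvalues** of the 2×2 gyration tensor use the closed form in the
  vectorized paths and `eigen(symmetric = TRUE)` in the reference path;
  round-off negatives are clamped to zero. The two paths are cross-checked
  in the tests. Equal eigenvalues need no tie-break — $\alpha$ is symmetric
  in them.
* **Degenerate tracks** (a single visited point) get $\alpha = 0$, the
  confined limit, with a flag so callers can exclude them; segmentation
  maps degenerate runs to diffusion.
* **Lag cap**: admissible lags are $1 \ldots \lfloor f N\rfloor$ steps for
  a cap fraction $f$; at the default $f = 0.1$ a track needs at least 11
  frames, and the error message says so.
* **Remainder frames** join the last segment rather than being dropped, so
  label tiling is exact for any track length.
* **Ensemble `v`**: per-track $\hat v$ values are combined on the $v^2$
  scale (the model's linear parameter) and the root taken afterwards;
  averaging $\hat v$ directly is biased low because the square root of a
  noisy nonnegative estimate shrinks toward zero.
* **Model-selection ties** and untestable cases resolve to Brownian —
  parsimony, and the conservative choice for claiming active transport.
* **Reproducibility**: every stochastic function takes a seed and restores
  the caller's RNG state; `run_pipeline()` writes tables stamped with a
  config hash and the master seed, and two runs with the same inputs are
  byte-identical.

Problem sizes used by the test suite were chosen to give comfortable
statistical margins at interactive runtimes: 10⁴ tracks of 100 frames for
the 4/7 ensemble check, 10⁴ Brownian tracks per length for the tail
calibration, and 200 tracks of 300 frames for parameter recovery.

## Limitations

* Only the two stated MSD models are fitted; anomalous exponents
  ($\mathrm{MSD}\sim\tau^{\gamma}$) and confined-diffusion models are out
  of scope, as are HMM or changepoint segmentation alternatives — fidelity
  to the rule-based algorithm is the point.
* The F-test's nominal level ignores MSD autocorrelation (see above); use
  the segmentation, not the global model selection, when false "flow" calls
  are costly.
* Thresholds depend on the analysed ensemble; comparing conditions requires
  either shared thresholds (pass `thresholds =`) or awareness that each
  condition is classified against its own speed distribution.
* 2D projections of 3D motion bias both $D$ and $\alpha$; the package makes
  no attempt to correct for this.
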
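# sptmotion

Motion-mode classification for 2D single-particle tracking of intracellular
vesicles.

Fluorescently labelled cargo — lipoplex-loaded endosomes, for instance —
moves through the cytoplasm either by Brownian diffusion or by
motor-driven, microtubule-associated "flow" transport, usually as
stop-and-go alternation of the two. `sptmotion` takes trajectory tables
(track id, frame, x, y in µm; e.g. TrackMate exports at 1 frame/s for 2–5
min) and quantifies which mechanism is at work, globally and locally:

* **MSD analysis** — time-averaged mean square displacement per track with
  lags capped at 10% of the track time, and constrained least-squares fits
  of the two transport models

  `MSD(τ) = 4Dτ + ε`  (Brownian)  and  `MSD(τ) = 4Dτ + (vτ)² + ε`  (flow),

  with `D` the diffusion coefficient (µm²/s), `v` the drift speed (reported
  in µm/min) and `ε ≥ 0` the localization-error offset; nested-model
  selection by F-test.
* **Shape analysis** — gyration tensor and asphericity
  `α = (λ₁−λ₂)²/(λ₁+λ₂)²` ∈ [0, 1] (0 = confined/isotropic, 1 = a straight
  line); the ratio-of-means ensemble estimator has the theoretical Brownian
  value 4/7 ≈ 0.57 in 2D.
* **Monte-Carlo calibration** — the probability that a *pure Brownian*
  track exceeds an asphericity threshold, per track length; at the default
  threshold 0.8 this false-positive rate is ~3–8% over 10–300 frames.
* **Segmentation** — the local classifier: 3-frame segments, ensemble speed
  thresholds at 70% of the mean absolute segment speeds, runs of ≥ 2
  above-threshold segments become flow domains when their local asphericity
  exceeds 0.8; population fractions (time-weighted and track-dominant) per
  condition.
* **Colocalization** — Manders M1 (pixel-based, optional Costes-style
  threshold) and object-based percent-colocalized spots.
* **Synthetic tracks** — a ground-truth stop-and-go generator so every
  stage is testable without imaging data, plus Stokes–Einstein and
  Smoluchowski conversions for the accompanying colloidal characterization.

Everything is tidyverse-shaped: functions take a data frame first, return
tibbles, and chain with the pipe; fitted objects have `tidy()`/`glance()`
and `autoplot()` methods.

## Worked example

Two simulated conditions mimic the regimes of interest: a
diffusion-dominant formulation (`D = 1.0e-3` µm²/s, 200 of 250 frames
Brownian) and a transport-dominant one (`D = 3.7e-4` µm²/s, 200 of 250
frames flow at `v = 0.45` µm/min), 30 tracks each at 1 frame/s:

```r
library(sptmotion)
library(dplyr)

lfn_like <- simulation_spec(
  bind_rows(
    motion_domain("brownian", 200, D = 1.0e-3),
    motion_domain("flow",      50, D = 1.0e-3, v = 0.45)
  ),
  n_tracks = 30
)
dd_like <- simulation_spec(
  bind_rows(
    motion_domain("brownian",  50, D = 3.7e-4),
    motion_domain("flow",     200, D = 3.7e-4, v = 0.45)
  ),
  n_tracks = 30
)

report <- run_pipeline(
  list(LFN = lfn_like, DD = dd_like),
  config = analysis_config(seed = 1, calibration_lengths = c(10, 100, 300))
)

report$fits %>%
  group_by(condition) %>%
  summarise(D = mean(D), v = mean(v_um_min, na.rm = TRUE),
            flow_tracks = mean(model == "flow"))
#> # A tibble: 2 × 4
#>   condition        D     v flow_tracks
#>   <chr>        <dbl> <dbl>       <dbl>
#> 1 DD        0.000379 0.421       0.867
#> 2 LFN       0.000918 0.432       0.433
```

The per-track MSD fits recover the simulated magnitudes — `D ≈ 3.8e-4`
vs. `9.2e-4` µm²/s and `v ≈ 0.42–0.43` µm/min against a truth of 0.45 —
and model selection calls 87% of the transport-dominant tracks "flow"
versus 43% of the diffusion-dominant ones. The calibration table behind
the segmentation threshold is part of the same report:

```r
glance(report$calibration)
#> # A tibble: 1 × 6
#>   alpha_thr min_tail_prob max_tail_prob n_lengths n_sims  seed
#>       <dbl>         <dbl>         <dbl>     <int>  <int> <dbl>
#> 1       0.8        0.0402         0.069         3  10000     1
```

i.e. a pure Brownian track of 10–300 frames exceeds asphericity 0.8 only
4–7% of the time, which is the false-positive rate bought by the default
`alpha_thr = 0.8`. Frame-level flow fractions (`report$fractions`) are
deliberately conservative at drifts as slow as 0.45 µm/min — a 7.5 nm/s
drift under 27 nm diffusive steps; see the vignette for why, and
`plot_tracks()`, `plot_msd()`, `plot_fractions()` for the standard figures.

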
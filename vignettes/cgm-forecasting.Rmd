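---
title: "How much CGM history does a short-term glucose forecast need?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How much CGM history does a short-term glucose forecast need?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Wearable flash glucose monitors (FGM) report interstitial glucose every
minute. A forecaster running on such a device must decide three things:
how much history to keep (the *past sliding window*, PSW, in hours — the
data **volume** `n`), how often to sample it (the *sampling frequency*, SF,
in minutes — the **velocity** `n/T`), and how far ahead to predict (the
*prediction horizon*, PH, in minutes). `cgmcast` provides a tested harness
for mapping forecast error over (PSW, SF, PH) grids with per-patient
univariate models, together with a synthetic FGM cohort generator, so the
whole trade-off study can be reproduced end to end from a seed.

At each forecast origin `t`, the trailing window
`x_1, ..., x_n` (`n = PSW * 60 / SF`) is the training set; a patient-centric
model is fit on it and asked for a point forecast of the reading at
`t + PH`; the forecast is scored against the reading the sensor actually
produced. The window then slides forward FIFO-style (drop `x_1`, append the
new reading) and the procedure repeats — rolling-origin evaluation. Errors
are summarized per patient as RMSE and aggregated across patients by
unweighted mean and sample standard deviation; per-record errors are never
pooled across patients.

## The synthetic cohort

Real CGM study data are personal medical data and are typically not
redistributable, so the package ships a generative stand-in whose *sensor*
behaviour is calibrated to published FGM accuracy figures. Ground truth for
each patient is

* a baseline level (default 120 mg/dL),
* a circadian sinusoid (default amplitude 15 mg/dL, peaking at 08:00 — a
  dawn-phenomenon-like rise),
* one gamma-shaped excursion per meal slot (four slots: 07–09, 12–14,
  16–17, 20–22 h, emulating a regulated daily routine), peak height drawn
  uniformly from 40–120 mg/dL, peaking 45 min after the meal and decaying
  with the ~60-min half-life of fast-acting insulin,
* Ornstein–Uhlenbeck noise (θ = 0.01 /min, σ = 0.8 mg/dL·min^-1/2,
  stationary SD ≈ 5.7 mg/dL) for short-range autocorrelated variability,

clamped to 20–600 mg/dL. Per-patient variability is emulated by jittering
baseline, circadian amplitude and meal sizes ±20%. These choices reproduce
the *qualitative* structure short-term forecasters exploit — smooth local
dynamics, meal bumps, daily cycles — not any particular patient population;
defaults put the cohort mean in the 140–170 mg/dL range typical of type 1
diabetes under basal-bolus therapy.

The sensor model then applies, in order: a first-order exponential lag
filter (time constant 7.5 min, the midpoint of the 5–10 min interstitial
delay), multiplicative Gaussian reading noise, and clipping to the
40–500 mg/dL reporting range with `low`/`high` saturation flags. The noise
scale is an *analytic inversion* of the published sensor accuracy: for
`reading = truth * (1 + eps)` with `eps ~ N(0, sigma^2)`, the mean absolute
relative difference is `E|eps| = sigma * sqrt(2/pi)`, so
`sigma = 0.114 / sqrt(2/pi) = 0.1429` makes the 11.4% MARD a *testable
output* of the simulator rather than an assumption:

```{r, eval = FALSE}
library(cgmcast)
truth <- simulate_ground_truth(sim_params(), duration_days = 7, seed = 1)
sens  <- apply_sensor_model(truth, sensor_params(lag_tau_min = 0), seed = 2)
compute_mard(sens, truth)   # ~0.114
```

What the generator does **not** emulate: meal-size/insulin-dose coupling,
exercise, sensor dropout and compression artifacts, drift between
calibrations, or any inter-day adaptation. Passing grid results on this
cohort therefore demonstrate that the harness measures what it claims to
measure and that qualitative orderings (error grows with horizon) come out
— not that any particular RMSE level transfers to real patients. Note one
consequence of the calibration: the multiplicative noise floor
(≈ 0.1429 × glucose, i.e. ≈ 20 mg/dL at 150 mg/dL) is irreducible for any
forecaster scoring against the *sensor* reading, so absolute RMSEs on the
synthetic cohort sit above those reported for real sensors, whose
minute-to-minute error is strongly autocorrelated rather than independent.

## Forecasters

All methods are univariate and patient-centric, fit on one window at a
time.

* **ARIMA(p,d,q)** — the differencing order `d ∈ {0,1}` is chosen by a
  Phillips–Perron unit-root test (information criteria are not comparable
  across `d` because differencing changes the sample; the unit-root-first
  scheme is standard automatic-selection practice), then `(p,q) ≤ (3,3)` by
  AICc under conditional-sum-of-squares fitting. Forecasts are iterated
  (model-native recursion). Constant windows degenerate to the mean
  predictor; wholesale convergence failure falls back to ARIMA(1,1,0).
* **Random forest** — direct strategy: the target `h` steps ahead is
  regressed on the `m = 6` most recent values (time-delay embedding within
  the window). Defaults: 500 trees, `mtry = ceiling(m/3)`, minimum node
  size 5, seeded for reproducibility.
* **Support vector regression** — same embedding; RBF kernel, `C = 1`,
  `epsilon = 0.1`, `gamma = 1/m`, with features and target z-scored by the
  window's own statistics (stored for exact inversion).
* **Naive persistence** — last observed value; the baseline any horizon
  method must beat.

`m = 6` guarantees at least one training pair at the smallest study window
(`n = 12`: PSW 3 h at SF 15 min) for every horizon. The direct strategy for
the ML methods avoids compounding errors through recursive resubstitution;
ARIMA recursion is native to its state-space form. Hyperparameters are
fixed and documented rather than tuned per window: per-window tuning would
be dominated by refit cost and is deliberately out of scope.

## Numerical and design choices

* **Horizon steps.** Horizons are evaluated `h = PH/SF` steps ahead. When
  PH is not a multiple of SF (PH 15 or 45 min at SF 10), the forecast is
  evaluated at the next on-grid step (`h = ceiling(PH/SF)`, so an effective
  20 or 50 min), and the effective horizon is recorded on every prediction
  record; `ph_exact = TRUE` turns such pairs into errors instead. This
  keeps the velocity experiment's full 3 SF × 4 PH grid without inventing
  off-grid observations, at the price of slightly pessimistic cells.
* **Shared burn-in.** Within a grid run the first forecast origin is placed
  after the *largest* PSW in the run, so every cell is scored on the
  identical origin set and cells differ only in what the model saw, never
  in when it was asked.
* **Refit cadence.** `refit_every = k` refits each model at every k-th
  origin and reuses it in between; every origin is always evaluated. ARIMA
  reuses its coefficients but re-filters them on the current window (a
  single Kalman pass, no re-optimization) so the forecast is issued from
  the current origin. Order selection runs at the first refit of each cell
  evaluation and the selected order is kept for subsequent refits, which
  re-estimate coefficients only — repeating the grid search at every refit
  changes selected orders only rarely and multiplies cost ~16-fold.
* **Resampling** is instantaneous point-sampling anchored at the trace
  start (FGM values are instantaneous estimates; averaging would create a
  different, smoother signal).
* **Degenerate inputs.** Constant windows/targets fall back to mean
  predictors with a message; forecasts are clipped to 20–600 mg/dL as a
  sanity bound; windows with internal gaps larger than the sampling
  interval are not interpolated (imputation is out of scope).
* **Ties** in the optimal-PSW query break toward the smaller window —
  when equal, less memory is the better engineering answer.
* **Seeds.** A master seed derives per-patient substreams
  (`seed_i = (seed + 7919 i) mod 2^31-1`; `+1`/`+2` for the truth and
  sensor streams), so any patient regenerates in isolation and a run is
  fully reproducible from its JSON run config.

## Problem sizes used in the shipped checks

The package's own test suite exercises the full volume-experiment grid
(5 PSW × 4 PH × 3 methods) on a 5-patient × 2-day cohort with
`refit_every = 12`, and the horizon-monotonicity property (mean RMSE
non-decreasing in PH for every method) on a 5-patient × 14-day cohort at
PSW 6 h / SF 15 min with `refit_every = 4` (hourly refits; much longer
cadences leave models a day stale, and staleness error then swamps the
horizon effect the property is about) — sizes chosen so the whole
suite runs comfortably on a laptop CPU while still covering every grid
cell and >10^3 forecast origins per patient. A full 25-patient × 14-day
cohort at `refit_every = 1` reproduces the study design faithfully and is
a matter of hours, not days, on a workstation.

## Known limitations

* The synthetic cohort cannot validate *absolute* error levels against any
  real population; only orderings and harness correctness.
* CSS-fitted ARIMA coefficients are unconstrained; rare explosive fits are
  tolerated because forecasts are clipped and refits are frequent.
* The sensor noise is white; real FGM error is autocorrelated within
  minutes, which flatters persistence-style methods less than it should.
* Missing-data handling is limited to refusing gapped windows; no
  imputation.
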
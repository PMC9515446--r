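---
title: "Methods: distance estimation, gait metrics and selection in coopergait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance estimation, gait metrics and selection in coopergait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopergait)
```

`coopergait` analyses the 12-minute Cooper run test recorded with a chest-worn
GNSS receiver (10 Hz position and ground speed) and foot-worn inertial
measurement units (512 Hz). It covers four stages — distance estimation,
per-cycle gait parameters, a 175-metric feature grid, and statistical metric
selection — plus a synthetic-data module that emulates the cohort, the track
trajectories and the gait streams so that every stage is testable without
real recordings. This vignette explains the models, the tunable parameters
and the design decisions; it states no empirical result that the package's
tests do not themselves compute.

## Distance estimation

Five estimators of the distance covered in 12 minutes are implemented:

* **D_S** — trapezoidal strapdown integration of the GNSS ground speed, after
  outlier removal;
* **D_C** — summation of Haversine distances between consecutive fixes
  (sphere radius 6,371 km, configurable);
* **D_L** — lap counting: on an oval track the latitude shows one peak per
  lap, so with `n_p` peaks, mean inter-peak spacing `d_a` (samples) and
  `l_s` samples outside the peak-to-peak span, the distance is
  `(n_p - 1) * L + l_s / d_a * L` with `L` the lap length (default 400 m,
  adjustable for outer lanes);
* **D_LS**, **D_LC** — hybrids: whole laps from peak counting plus the
  partial segments before the first and after the last peak measured by
  strapdown integration or coordinate summation respectively.

Speed outliers are samples more than `k_sd` (default 2) standard deviations
from the mean of a centred sliding window (default 60 s); they are replaced
by linear interpolation between the nearest retained neighbours. Windows are
truncated at the trace edges and flagged edge samples take the nearest
retained value, a pure extrapolation — the interior-interpolation rule does
not define them otherwise. Note that on a Gaussian signal a 2-SD rule flags
roughly 5% of samples by construction; it is an outlier clamp, not a smoother.

Peak detection uses a light moving-average pre-smoothing (2 s), a minimum
peak height of half the latitude amplitude and a minimum separation of
`min_lap_time_s` (default 50 s, i.e. no lap faster than 50 s). Neither
parameter is critical on track data, where the latitude amplitude is two
orders of magnitude above the positional noise; both are exposed because
other venues may need them.

Estimators are compared against a reference distance with mean absolute
error, signed bias, Bland–Altman 95% limits of agreement, the standard
deviation (CV) of the percentage error, and median ± IQR percentage error.

## Gait parameters

The right foot's sagittal angular velocity is segmented at mid-swing peaks
(prominence at least 40% of the 90th-percentile swing amplitude, refractory
period 0.4 × the median cycle time estimated in a first pass). Per cycle:

* **GT** (gait cycle time) — the inter-mid-swing interval;
* **CT** (contact time) — the longest run of samples with gyroscope norm
  below 50 °/s (the foot is nearly stationary on the ground); cycles without
  a stationary phase of at least 50 ms are flagged and excluded;
* **ST** (swing time) — `GT - CT`, enforced per cycle;
* **FT** (flight time) — with a single foot's signal the true flight time
  (toe-off to contralateral initial contact) is unobservable, so the raw
  path estimates `FT = GT/2 - CT`, clamped at zero — the symmetric-gait
  approximation. Streams of precomputed per-cycle values carry FT directly.
* **DF** (duty factor) — `CT / GT × 100%`;
* **PSV** — on the raw path, the peak gyroscope norm in the cycle, an
  approximation to the orientation-derived peak swing velocity. Foot strike
  and eversion angles (FSA, FEA) require orientation estimation and are not
  re-derived from raw signals; they enter via the per-cycle stream path.

**Vertical stiffness** follows the sine-force spring-mass model: the
vertical ground reaction force during contact is `F(t) = F_max sin(pi t /
t_c)`; the impulse balance over one step gives
`F_max = m g (pi/2)(t_f / t_c + 1)` and the centre-of-mass drop at
mid-stance is `dz = F_max t_c^2 / (m pi^2) - g t_c^2 / 8`, so
`VS = F_max / dz` (kN/m, g = 9.81 m/s²). The test suite checks the closed
form against an independent numerical integration of
`m z'' = F_max sin(pi t/t_c) - m g` from the landing velocity `-g t_f / 2`
over a grid `t_c` 150–350 ms, `t_f` 0–200 ms, mass 50–90 kg; agreement is
well inside 0.5% (the closed form is the exact solution of that ODE).

**Symmetry indices** use `SI = 2 |X_L - X_R| / (X_L + X_R) × 100%`, bounded
in [0, 200] and zero iff the sides are equal, computed for CT, FT, ST and
PSV on left/right cycle pairs. Pairing is by containment — a left cycle is
matched to the right cycle whose window contains its start — which on clean
data coincides with nearest-start matching capped at half a cycle (the left
foot strikes half a cycle after the right) but avoids the exact-boundary tie
of that cap; unmatched cycles are dropped and counted. The SI of the gait
cycle time itself is a validity check: both feet share one cadence, so its
median should be near zero (warning above 2%).

## The 175-metric grid

The first and last minute of the 12-minute run are removed (acceleration and
end-spurt effects); cycles are assigned to segments by the half-open rule
`[begin, end)` on their start time. Five time segments are used, in ordinal
minutes of the run: total (2nd–11th, i.e. [60, 660) s), steady (5th–8th),
start (2nd minute), end (11th minute), and delta. Three features apply to
each of 13 parameters (the nine above plus the four symmetry indices):

* **mean (mu)** — arithmetic mean over the segment;
* **variability (sd)** — the segment is split into consecutive
  non-overlapping windows of 10 cycles (remainder dropped; non-overlapping
  is a documented choice, the window definition admits either reading); the
  feature is the mean of the per-window sample standard deviations. With
  fewer than 10 cycles it is undefined and flagged. Not computed for the
  four asymmetry parameters.
* **slope (m)** — (last value − first value) / segment duration in minutes
  (10, 4, 1, 1 for t/sy/s/e); a single-cycle segment yields 0 by convention.

Delta is computed feature-wise as `feature(end) - feature(start)` — the
fatigue category explicitly uses mean, variability and slope *of* the delta
segment, which is only well-defined if delta differences the features, not
the raw cycles. The grid therefore holds `13 × 5 × 3 - 4 × 5 = 175` metrics.
Canonical names are `muVS_t`-style ASCII with a Unicode rendering (`μVSt`)
available; parsing inverts both.

Each metric belongs to exactly one category: *technique* (means of CT, FT,
VS, FSA, FEA, DF outside delta), *pace* (means of GT, ST, PSV outside
delta), *regularity* (variability features outside delta), *asymmetry*
(means of the SI parameters outside delta) and *fatigue* (all delta features
plus every slope). These rules partition the grid (24/12/36/16/87); a
precedence order (technique > pace > regularity > asymmetry > fatigue) is
implemented for safety but never fires.

## Metric selection

For each performance variable — maximal aerobic speed (MAS), speed at the
second ventilatory threshold (sVT2), and the Cooper average speed (CAS =
reference distance / 0.2 h) — the funnel is:

1. **z-scoring** across participants (sample n−1 sd; zero-variance columns
   become zero and are flagged);
2. **multicollinearity pruning**: within pairs with `|r| > 0.95` the metric
   from the longer time segment is kept (t > sy > s > e > d; of the two
   one-minute segments the start segment wins — a deterministic documented
   tie-break; same-segment ties keep the earlier column);
3. **target-correlation filter**: keep `|r| ≥ 0.3` against the performance
   variable. The absolute value is used deliberately: metrics that
   contribute negatively to performance must survive;
4. **LASSO with exhaustive leave-one-out cross-validation**: the penalty is
   chosen by the one-standard-error rule (fewest nonzero coefficients whose
   CV error is within one SE of the minimum — LOOCV is exhaustive, so the
   whole pipeline is deterministic given the data); coefficients below 5%
   of the total absolute weight are then pruned. Reported fit quality
   (cross-validated R² = 1 − SSE/SST over held-out predictions, RMSE) comes
   from the unpruned chosen-penalty predictions; there is no refit after
   pruning. R² is the CV determination coefficient, which can be slightly
   negative for uninformative models — a squared correlation is *not* used
   because under LOOCV the held-out intercept-only prediction is perfectly
   anti-correlated with the held-out observation, making cor² misleading on
   null data;
5. **Welch testing**: the 10 highest vs the 10 lowest performers by the
   variable, per-metric unequal-variance t-tests at p < 0.05 (uncorrected —
   the companion effect size is Cohen's d with pooled sd; Benjamini–Hochberg
   is available behind the `adjust` switch and the uncorrected default is
   flagged in the documentation because ~5% of null metrics will pass);
6. **profile**: per variable, the union of LASSO-selected and significant
   metrics; across the three variables, the intersection. Category
   contributions are shares of summed absolute LASSO weights.

CAS stands in for the reference distance when ranking participants: over a
fixed 12 minutes they are proportional, so groupings are identical.

## The synthetic-data module

The generators define the conditions under which the pipeline is exercised:

* **Cohort** (default n = 33): MAS uniform on 10.5–21.5 km/h (a mixed
  trained/recreational range of performance speeds); sVT2 = 0.918·MAS −
  0.63 + N(0, 0.8) km/h, slope/intercept consistent with the shipped linear
  distance equations; reference distance `D_ref = 0.88 × MAS × 0.2` km
  (runners sustain about 88% of MAS over 12 minutes). D_ref is
  deterministic in MAS by construction, so a D_ref-only regression on a
  synthetic cohort is exact — the scatter of real cohorts is not emulated.
  Mass is N(69, 10) kg truncated at 40 kg.
* **Track**: a 400 m stadium (straights 84.39 m, curve radius ~36.8 m)
  with straights oriented north–south so the latitude has one smooth apex
  per lap; metres map to degrees by a local tangent plane at the track
  origin (consistent with Haversine inversion to well under 0.01% over a
  400 m extent). The pacing shape is a fast first minute, a linear decay to
  minute 11 and an end spurt, normalised so the mean speed equals CAS.
* **GNSS noise**: independent Gaussian speed noise (sd 0.15 m/s); AR(1)
  positional noise per axis with stationary sd 1.5 m and a per-second
  coefficient of 0.95 (drift correlation time ~20 s — GNSS error wanders
  slowly; applying the coefficient per 0.1 s sample would mean ~0.5 m jumps
  between consecutive fixes and implausibly inflate any polyline length);
  isolated +6 sd speed spikes at rate 0.2%, sized to be unambiguously
  removable by the 2-SD filter. The `"field"` preset adds two
  per-participant terms that reproduce the between-runner spread seen in
  field recordings, where receiver drift differs from runner to runner: a
  multiplicative ground-speed bias (mean −2%, sd 3%, emulating Doppler
  drift and its typical underestimation) and a positional sd drawn
  uniformly from 0.5–2.5 m. Without such per-participant terms, zero-mean
  white speed noise averages out under integration and the strapdown
  estimator would — unrealistically — be the most precise method.
* **Gait streams**: per-cycle values are `baseline + drift × elapsed
  minutes + noise`, with `GT = CT + ST` enforced exactly per cycle; left
  values equal right values plus a side offset (driving the symmetry
  indices) and start half a cycle later. Baselines (CT 250 ms, FT 100 ms,
  GT 700 ms, VS 25 kN/m, FSA 15°, FEA 5°, PSV 600 °/s) are plausible
  literature values for trained runners — per-parameter cohort
  distributions are not published for this protocol, so these defaults are
  flagged as assumptions and are all overridable. The `"fatigued"` preset
  drifts in the directions acute fatigue pushes running form (CT up; FT,
  FSA, VS down). A planted-effect map can link any metric's generating
  parameter (baseline for means, drift for slopes/deltas, noise sd for
  variability) to a participant's performance variable, enabling
  end-to-end recovery tests.
* **Raw IMU traces**: a 512 Hz sagittal angular-velocity signal with one
  Gaussian mid-swing pulse per cycle, a moderate swing plateau, exact
  near-zero stance windows, and an impact burst on the accelerometer at
  each initial contact. Planted mid-swing times and stance windows are
  returned for oracle testing. This is a segmentation fixture, not a 6-DoF
  simulation: orientation dynamics, soft-tissue artefacts and sensor bias
  are absent, so passing tests demonstrate the correctness of the event
  logic, not robustness to every artefact of real IMU data.

What the synthetic data do *not* emulate: multipath GNSS physics, real
pacing idiosyncrasies, heart-rate/ECG channels, non-linear fatigue dynamics,
and the unpublished joint distribution of the real cohort's biomechanics.
Consequently the package's tests validate algorithmic correctness and
statistical calibration, not the reproduction of cohort-specific regression
tables, which require the original recordings.

## Numerical and testing choices

Problem sizes in the test suite are chosen to run comfortably on one CPU:
distance comparisons use 50 simulated participants; selection-recovery uses
50 replicates of n = 40 cohorts with 3 planted metrics among 30 noise
metrics (noise sd 0.2); planted effects are given equal dominant magnitudes
because with three drivers the per-metric population correlation with the
target is bounded by 1/sqrt(3) ≈ 0.58, so weaker effects sit against the
r ≥ 0.3 filter and recovery becomes a coin flip of sampling noise rather
than a property of the pipeline. Welch calibration uses 20 null cohorts ×
110 metrics (2,200 tests). All randomness is seeded; LOOCV has no fold
randomness at all.

Degenerate inputs are contracts, not crashes, wherever the field expects
them: constant latitude signals signal "lap methods unavailable"; fewer than
10 cycles make variability undefined (`NA`, listed as missing); a
non-physical spring-mass input (`dz ≤ 0`) yields `NA` for that cycle;
zero-variance targets and constant predictors are errors.

## A worked example

```{r example, eval = FALSE}
run <- run_pipeline(run_config(seed = 3))
run$distances$report[, c("method", "mae_m", "iqr_err_pct")]
run$selection$per_variable$mas$counts
run$selection$profile$metrics
```

The default configuration simulates 33 participants with performance-linked
gait effects, estimates their distances under the `"field"` noise preset,
extracts the 33 × 175 metric matrix and runs the full selection for MAS,
sVT2 and CAS. The whole run takes a few seconds.

## Known limitations

* The raw-signal contact detector is a simplified stillness detector
  validated only against synthetic fixtures; production foot-IMU pipelines
  use richer event detection with orientation fusion.
* Flight time from a single foot is an approximation (see above).
* The shipped regression coefficients are published constants; the package
  reproduces their *form* on synthetic cohorts, not their values, which
  belong to the original cohort.
* Percentage category contributions depend on the LASSO penalty chosen by
  the one-SE rule and can shift between near-threshold metrics on small
  cohorts.
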
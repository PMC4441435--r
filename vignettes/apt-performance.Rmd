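---
title: "Assessing whole-lake acoustic positional telemetry with aptperf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing whole-lake acoustic positional telemetry with aptperf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptperf)
library(dplyr)
```

## The problem

Acoustic positional telemetry (APT) tracks tagged fish in lakes with an
array of hydrophones: each transmitter emits coded pings on a fixed burst
interval, and when a ping is detected by at least three hydrophones a 2-D
position can be estimated from the differences in its times of arrival
(TDOA). How well such a system performs — what fraction of pings become
positions (efficiency, or data yield), how far positions sit from the truth
(accuracy), how much they scatter (precision), and how much apparent
movement positioning error induces in a stationary animal (false movement)
— depends strongly on habitat: vegetation attenuates the signal, and
multipath reflections corrupt arrival times. `aptperf` implements the full
evaluation pipeline used in whole-lake field assessments, together with a
synthetic-data generator that emulates the trials such an assessment runs,
so every stage can be exercised, tested and calibrated without field data.

The pipeline has five stages, each usable on its own tibbles:

1. **lakesim** — synthetic lakes, arrays, transmitters, detections, tows,
   sensors (`apt_lake()`, `build_scenario()`, `apt_simulate()`).
2. **positioning** — TDOA multilateration with quality metrics
   (`solve_position()`, `compute_quality()`, `position_all()`).
3. **trackproc** — quality filtering and grid HMM smoothing
   (`apply_quality_filter()`, `hmm_smooth()`, `run_filter_pipeline()`).
4. **perfmetrics** — per-trial performance statistics
   (`stationary_accuracy()`, `efficiency()`, `false_movement()`,
   `tow_accuracy()`, `track_length()`).
5. **habstats** — GLS habitat models with post-hoc letters and
   back-transformed summaries (`fit_gls()`, `posthoc_pairwise()`,
   `backtransform_summary()`, `depth_regression()`).

`apt_assess()` chains them end to end.

## The synthetic study system

Two shipped scenarios emulate the two kinds of installation such
assessments compare:

* **lake1** — a 25 ha lake (elliptical basin, maximum depth 7.6 m, mixed
  water column at 17.1 °C) with 20 *wireless* hydrophones in two rings plus
  a centre unit (mean pairwise spacing ≈ 265 m). Wireless loggers run on
  their own clocks: each starts with an offset (± 0.05 s) and drifts
  (± 2·10⁻⁶ s/s), and is clock-synchronised only in processing, from beacon
  transmitters at known positions (`apply_clock_model()`). Transmitters are
  combined acoustic–radio tags: burst interval 9.2 s, with every third
  emission relayed as a radio signal and therefore absent from the acoustic
  record. All six habitat categories are present: dense submerged
  macrophytes (SD), above submerged macrophytes (SA), shallow open water
  (OS), deep open water (OD), loose (EL) and dense (ED) emergent
  macrophytes. 90 stationary deployments are stratified over the six
  habitats in proportion to a field design of this type, plus 6 tow tests
  at 0.58 m/s.
* **lake2** — a 1 ha pond (maximum depth 8 m, 5.4 °C) with 8 *cabled*
  hydrophones on one ring (spacing ≈ 65 m), all clock-synchronised by a
  single datalogger (no clock error). Burst interval 2.56 s, no radio
  relay. Submerged macrophytes are absent, so 50 deployments cover
  OS/OD/EL/ED, plus 22 tow tests at 0.43 m/s.

The speed of sound is computed from temperature with the fifth-order
fresh-water polynomial (`sound_speed()`); both lakes are simulated fully
mixed, so a single sound speed per scenario suffices and no thermocline or
stratified propagation is modelled.

### Detection model and its calibration

Whether a hydrophone detects an emission is Bernoulli with a logistic range
response `p = 1 / (1 + exp((r − r50[habitat]) / k))`, where `r50` is the
habitat-specific 50 %-detection range. This functional form is the
package's own choice — field studies constrain only the *ordering* (denser
structure attenuates more, so `r50(ED) < r50(EL) < r50(open water)`). The
shipped `r50` defaults were calibrated once, on the shipped geometries, so
that raw data yield lands near 70 % for deep open water and near zero in
dense emergent vegetation — the orders of magnitude such systems show in
the field — and then frozen; they are defaults of the generator, not
estimates of any particular lake.

Detected arrival times carry Gaussian jitter (`toa_jitter_sd`, default
10⁻⁴ s ≈ 0.15 m of range) plus, with probability 0.05 by default, an
exponential multipath delay (mean 5 ms ≈ 7 m). Multipath delays are always
positive — a reflected path is longer — and they are what makes the
position-error distribution heavy-tailed, motivating the t-distributed
observation model in the smoother. Ground truth is observed through a DGPS
with isotropic Gaussian error of sd 0.2 m (the instrument's stated bound
used as a standard deviation); tow-truth is sampled at 1 Hz. Pressure
sensors report unitless values clamped to [0, 100]; the raw reading is
`depth × scale` plus Gaussian sensor noise whose default (0.6 raw units ≈
0.06 m) reproduces the within-trial spread reported for such sensors, and
the true scale differs from the nominal one by about 1 %, so the
calibration regression has something real to estimate.

All randomness flows through one seed: every trial derives its own
substream deterministically from `(seed, trial id)`, so identical
`(scenario, seed)` pairs reproduce byte-identical data streams and
simulation refuses to run without an explicit seed.

### Radio-skip convention

With 1-based emission indices, indices divisible by 3 are the radio
emissions. Field descriptions say only "every third signal"; the phase
relative to deployment start is not knowable, so it is a documented,
configurable convention. The emission window is half-open: emission `k` is
included iff `t_start + k·burst ≤ t_end`.

## Positioning

All TDOAs of one emission are anchored to the earliest-arrival hydrophone
(n − 1 independent differences), which eliminates the unknown emission
time. The position minimises the sum of squared TDOA residuals by damped
Gauss–Newton. Because the hyperbolic objective is multimodal, the solver
starts from a coarse 20 × 20 grid over the lake bounding box and refines
from up to four well-separated low-objective cells, keeping the best basin;
non-convergence after 50 iterations or collinear geometry is *flagged*
(`degenerate`), never silently returned. Three-hydrophone fixes are
generically two-fold ambiguous (two hyperbola intersections); the solver
returns the best-fitting basin, which is one reason real pipelines weight
redundancy (RN below) so heavily.

Arrays larger than eight hydrophones are processed as overlapping ad hoc
8-hydrophone sub-arrays (13 for lake1), mirroring the 8-hydrophone limit of
the positioning software such systems use; one emission can therefore yield
several fixes whose estimated timestamps differ slightly, and
`reconcile_timestamps()` re-stamps fixes of one transmitter lying within a
tolerance (default a quarter burst interval) to their earliest member so
the smoother sees one timestamp per emission.

### Quality surrogates

Vendor software ships proprietary per-fix quality numbers (DOP, CN, RN).
Their formulas are not public, so `aptperf` defines documented surrogates
with the same filtering semantics:

* **DOP** — with `G` the matrix of unit-vector differences against the
  anchor and TDOA noise covariance ∝ `I + 11′` (the anchor's jitter is
  shared by every difference), the unit-noise covariance of the estimator
  is `Cov = (G'G)⁻¹G'(I + 11′)G(G'G)⁻¹` and `dop = sqrt(trace(Cov)/2)` —
  the exact per-axis error amplification of the solver actually used. The
  predicted total RMS scatter under jitter sd σ is `√2·dop·c·σ`, an
  identity the test suite verifies by Monte Carlo. The per-axis convention
  puts good open-water geometry near dop ≈ 1, so the customary thresholds
  (DOP < 10 permissive, DOP < 1 strict) have comparable semantics; the
  vendor's exact scaling is unknowable.
* **CN** — ratio of the largest to smallest singular value of `G`;
  infinite for collinear geometry.
* **RN** — detection redundancy `n − 3`. The customary thresholds RN > 0
  and RN > 1 then mean ≥ 4 and ≥ 5 hydrophones. This is a surrogate: the
  vendor's "reliability number" is undocumented.

## Filtering and smoothing

Two filter stages mirror field practice: a permissive **raw** filter
(DOP < 10, CN < 10, RN > 0, plus deletion of fixes outside the lake
perimeter where a perimeter is supplied) and a **strict** filter (DOP < 1,
CN < 10, RN > 1) ahead of smoothing. Published descriptions phrase the
thresholds as "values for exclusion" while listing the same inequalities as
their strict "high-quality" filter; `aptperf` reads the inequalities as
*retention* conditions, the only reading under which the strict filter is a
subset of the raw one. This interpretation is deliberate and confined to
`filter_spec()`.

The smoother is a hidden Markov model on a regular grid masked to the lake:
movement is a Gaussian random walk with per-axis variance `2·D·Δt` between
consecutive observation timestamps (irregular gaps from missed detections
are handled by the Δt scaling; nothing is imputed), and each fix is an
isotropic bivariate t observation, `∝ (1 + ‖z − m‖²/(ν σ²))^(−(ν+2)/2)`.
Mass diffusing across the shoreline is absorbed, so the smoother is exact
for the shore-truncated movement model. Forward–backward smoothing yields a
posterior per timestamp; its **mean** (not the mode) is the smoothed
position, and the number of positions never changes. Duplicate sub-array
fixes sharing a timestamp enter as a product of observation likelihoods.

Defaults: grid spacing 2 m (lake1) and 0.5 m (lake2) — below the accuracy
being measured; ν = 3, a strongly heavy tail, because multipath produces
gross outliers (ν is not identifiable from clean data and no field value
exists; it can be fitted); D = 0.05 m²/s for stationary tags and 2 m²/s for
tows (a boat at ~0.5 m/s needs that much process variance per burst).
`fit_smoother_params()` maximises the forward likelihood over any subset of
(D, σ, ν) by a log-scale grid search refined with L-BFGS-B; the test suite
demonstrates 25 %-relative recovery of D and σ at 500 fixes. Whole-lake
grids are wastefully large for a single trial, so `apt_assess()` builds a
local grid around each trial's fixes (padded 20 m, clipped to the lake).

## Performance metrics

Per trial (the sampling unit): efficiency = 100 × positions/emitted
acoustic signals, after deduplication to one position per emission
(sub-array duplicates never inflate yield; radio-relayed emissions are not
in the denominator by default, configurable); accuracy = mean Euclidean
distance to the DGPS truth; precision = the n−1 standard deviation of those
distances; false movement = mean distance between consecutive positions of
a stationary tag, extrapolated to an hour by
`accumulate_false_movement()`. Tow accuracy uses exact point-to-segment
minimisation against the DGPS polyline, and estimated track length is
compared with the truth length: a stationary tag has positive estimated
length against zero truth (pure overestimation), while a curved path
sampled with gaps is shortened by the chord inequality — the sign of the
length bias is regime-dependent, which the tests check on both regimes.
Trials with no positions count efficiency 0 but are excluded from
accuracy/precision models.

## Habitat statistics

Efficiency (as a proportion) is arcsine-square-root transformed — the
standard variance-stabilising reading of "arcsine-transformed"; the plain
`asin(p)` variant is switchable — and accuracy and precision are
`log(y + 0.1)` transformed (natural log). Habitat enters as a fixed factor
in a group-means model fitted by maximum likelihood; a per-habitat variance
structure is estimated by iterative feasible GLS and retained, under the
`"auto"` policy, iff the likelihood-ratio test against the homogeneous
model has p < 0.05 (AIC is also reported; the LRT is the retention
criterion). Habitat levels with fewer than four trials yielding positions
are excluded from accuracy/precision fits. The implementation is exact for
this model class (it reduces algebraically to weighted group means) and is
cross-checked in the tests against `nlme::gls` with `varIdent`.

Post-hoc comparisons shift the baseline level through all groups and read
off the contrasts — for a one-factor model this is algebraically the
difference of cell means with standard error `√(s²ₐ/nₐ + s²ᵦ/nᵦ)` — with
Wald (normal) p-values and no multiple-testing correction by default
(plain pairwise comparisons; a `p_adjust` argument exists). Letters mark
maximal runs of mutually non-significant levels (greedy insert-and-merge
over the mean-ordered levels). Summaries are back-transformed: mean =
inverse transform of the coefficient, band = inverse transform of the
coefficient ∓ that group's residual sd — asymmetric by construction, with
out-of-domain endpoints clamped and flagged.

The depth-sensor check regresses true deployment depth on reported depth
through the origin (`depth_regression()`), reporting the slope, its
standard error, the uncentered R², and confidence/prediction intervals.

## A worked run

```{r run, eval = FALSE}
scenario <- build_scenario("lake2", seed = 7)
sim <- apt_simulate(scenario)
assessment <- apt_assess(scenario, sim)
assessment
performance_report(assessment, "filtered")
autoplot(assessment, response = "accuracy_m")
```

Problem sizes are configurable; the shipped defaults (trial durations of
600 s for lake1 and 240 s for lake2, full trial counts) run a complete
scenario assessment in minutes on one core, and the examples and tests use
smaller stratifications of the same generator. The test suite's acceptance
checks run the heavier designs: 50-trial smoothing comparisons, 20-geometry
Monte-Carlo DOP validation, 1000-replicate null calibration of the
post-hoc procedure.

## What passing tests do and do not show

The generator reproduces the statistical *structure* the analysis assumes
— habitat-ordered detection ranges, heavy-tailed TOA error, wireless clock
drift, DGPS-level truth error, burst schedules with radio skips — not any
particular lake. Real systems add effects deliberately out of scope:
thermoclines and stratified sound speed, bathymetry-dependent multipath
geometry, transmitter collisions and code misassignment, biofouling drift
in detection range. Passing tests therefore demonstrate that the pipeline
is correct and well calibrated under its stated model, and that the
field-style conclusions (filtering + smoothing improves accuracy;
efficiency declines with structural complexity; track-length bias is
regime-dependent) emerge for the right reasons — not that any specific
field value would be reproduced.

## Numerical choices and degenerate inputs

* Solver: convergence tolerance 10⁻⁴ m on the step, 50 iterations, step
  halving to 2⁻²⁰ before declaring non-convergence; sub-metre residual
  basins are disambiguated by multi-start.
* HMM: likelihoods are renormalised every step; an observation farther
  than `6σ√ν` from every unmasked cell is treated as near-uninformative
  with a warning rather than zeroing the posterior.
* GLS: per-group variances floored at 10⁻¹²; groups need ≥ 2 observations
  or the fit errors (variance inestimable).
* Fewer than 3 detections is an error (`solve_position()`); fewer than 2
  positions give `NA` precision and false movement; zero-position trials
  keep efficiency 0 and `NA` accuracy.
* `reconcile_timestamps()` must use a tolerance below half the burst
  interval or distinct emissions could merge; `apt_assess()` uses a
  quarter.
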
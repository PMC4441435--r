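# aptperf

Performance assessment of whole-lake **acoustic positional telemetry**
(APT) systems, as a reusable, tested R pipeline.

APT arrays track tagged fish by detecting coded acoustic pings on several
hydrophones and estimating 2-D positions from the **time differences of
arrival** (TDOA): a ping heard by hydrophones at positions `p_i` with
arrival times `t_i` constrains the source `x` by hyperbolae
`c·(t_i − t_a) = ‖x − p_i‖ − ‖x − p_a‖`, where `a` is the earliest-arrival
(anchor) hydrophone and `c` the speed of sound. Field evaluations of such
systems deploy stationary and towed transmitters with DGPS ground truth
across habitat strata and summarise, per trial:

* **efficiency** (data yield) — % of emitted pings yielding a position,
* **accuracy** — mean Euclidean distance to truth,
* **precision** — SD of those distances,
* **false movement** — mean displacement between consecutive fixes of a
  stationary tag (apparent movement created by positioning error),

then model each against habitat with generalized least squares
(arcsine-square-root efficiency, `log(y + 0.1)` accuracy/precision,
per-habitat variances kept when a likelihood-ratio test supports them,
baseline-shifting pairwise post-hocs with letter displays).

`aptperf` implements the entire chain — a synthetic-data generator for two
emulated study lakes (a 25 ha lake with 20 wireless hydrophones on 9.2 s
burst with every third signal radio-relayed, and a 1 ha pond with 8 cabled
hydrophones on 2.56 s burst), a multi-start damped Gauss–Newton TDOA
solver with per-fix quality surrogates (DOP/CN/RN), two-stage quality
filtering, a grid hidden Markov model smoother with t-distributed
observation noise (heavy tails absorb multipath outliers), the trial
metrics, and the habitat statistics — so every stage can be exercised and
validated without field data. See the methods vignette
(`vignettes/apt-performance.Rmd`) for the models, parameter defaults and
design choices.

## Worked example

```r
library(aptperf)

scenario <- build_scenario("lake2", seed = 7,
                           trial_duration = 120,
                           stationary_counts = c(OS = 5, OD = 6, EL = 5),
                           n_tows = 2)
sim <- apt_simulate(scenario)
assessment <- apt_assess(scenario, sim)
assessment
```

```
<apt_assessment 'lake2'> seed 7
stationary trials, overall:
# A tibble: 2 × 5
  variant  n_trials mean_efficiency median_accuracy_m median_precision_m
  <chr>       <int>           <dbl>             <dbl>              <dbl>
1 filtered       16            19.3             0.279             0.0994
2 raw            16            55.1             0.571             0.839 
tow trials (filtered):
# A tibble: 1 × 4
  n_tows mean_efficiency mean_accuracy_m mean_length_ratio
   <int>           <dbl>           <dbl>             <dbl>
1      2            42.6           0.187             0.752
<apt_depth_fit> slope 1.0116 (se 0.0011), R^2 1.0000, n = 16
```

Reading this: the strict filter plus HMM smoothing halves the median
accuracy of the stationary trials (0.57 m → 0.28 m) and cuts the median
precision almost an order of magnitude (0.84 m → 0.10 m) at the cost of
yield (55 % → 19 % of emitted pings retained); the towed transmitter is
tracked to ~0.2 m with a track-length ratio below 1 (detection gaps cut
corners of a curved tow); and the pressure-sensor calibration recovers its
generating slope (1.01) from the simulated raw readings. `performance_report(assessment)` prints the
per-habitat back-transformed means with their asymmetric ±sd bands, and
`autoplot(assessment, response = "accuracy_m")` draws the raw-vs-filtered
habitat panels.

A thin command-line wrapper over the same functions ships in
`inst/cli/aptperf.R`:

```sh
Rscript inst/cli/aptperf.R simulate --scenario lake2 --seed 7 --outdir out/
Rscript inst/cli/aptperf.R assess   --scenario lake2 --seed 7 --outdir out/
```

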
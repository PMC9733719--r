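# pigflow

Drinker-use analytics for finisher pig pens: from water-flow sensor pulses to
hourly water use and drinker activations per pig, and on to the statistical
analyses this kind of precision-livestock data supports — diurnal rhythm and
age-trend modelling, treatment comparisons, drinking-cup preference, and
matched case-control analysis of pens around tail-damage events.

## Who this is for

Researchers and engineers working with pen-level water-flow meters in pig
facilities (or any paired-drinker livestock setting) who need a reproducible
pipeline for:

* calibrating pulse-count flow sensors (`calibrate_sensor()`,
  `recalibration_drift()`) and aggregating start/stop flow events to hourly
  per-pig water use and activation counts (`aggregate_hourly()`,
  `pen_level()`);
* removing sensor-fault outliers with a per-batch 4-residual-SD rule on a
  harmonic age-trend model (`clean_dataset()`);
* fitting the square-root-scale cosinor mixed model of the diurnal pattern
  (`fit_harmonic_mixed()`, `predict_diurnal()`, `daily_total()`);
* period × week × treatment analysis with backward elimination
  (`fit_period_model()`, `period_contrasts()`, `low_period_share_test()`);
* paired comparison of the feeder-side (F) and opposite (OF) cups
  (`location_means()`, `paired_location_test()`);
* matched tail-damage case-control analysis (`match_pairs()`,
  `window_summaries()`, `fit_event_model()`, `event_contrasts()`).

Because raw data of this kind are rarely deposited, the package includes a
seeded synthetic-study generator (`generator_config()`, `simulate_study()`)
that emulates the statistical structure such studies assume — three-wave
diurnal mean on the square-root scale, linear age trend, pen and day random
intercepts, within-day AR(1) hourly correlation, stocking effects in the
daytime peaks, cup-preference switching, sensor faults, and tail-damage
events with censoring — with ground-truth labels for every mechanism.

## The model in brief

Hourly use \(y\) for pen \(p\), day \(d\), hour \(t\) is modelled on the
square-root scale as

    sqrt(y_pdt) = mu0 + beta*d + sum_i (A_i + delta_i*d) sin(b_i*t + c_i)
                  + u_p + v_pd + e_pdt,

with fixed frequencies `b_i = i*2*pi/24` (24/12/8-h waves), random
intercepts for pen and day-within-pen, and AR(1) residuals across adjacent
hours. Estimation linearizes each wave via `u*sin(bt) + v*cos(bt)`;
amplitude/phase are recovered canonically (`amplitude_phase()`). Estimates
are back-transformed by squaring. Days are segmented into Peak 1
(06:00–11:59), Peak 2 (12:00–17:59) and Low (18:00–05:59) for the treatment
and event analyses.

## Worked example

```r
library(pigflow)

cfg    <- generator_config(study_days = 21)          # published fixed effects
roster <- generate_pen_roster(n_per_combination = 2, batches = 1, seed = 1)
sim    <- simulate_pen_hourly(roster, cfg, seed = 2) # 16 pens x 21 d x 24 h

cleaned <- clean_dataset(sim)                        # 4-residual-SD rule
cleaned$report
#> Outlier cleaning (4 residual-SD rule, sqrt scale)
#>     response n_input n_flagged n_retained fraction_flagged
#>        water    8064         0       8064     0.0000000000
#>  activations    8064         1       8063     0.0001240079

fit <- fit_harmonic_mixed(cleaned$data, "water")
fit
#> Harmonic mixed model of sqrt(water) [lme]
#>   n = 8064 hours, 16 pens, days 1-21
#>   initial mean 0.3426 (se 0.0035), daily trend 0.003486 (se 0.000157)
#>   wave 1 (24-h): A = 0.2745 (se 0.0011), c = -1.835 (se 0.004)
#>   wave 2 (12-h): A = 0.0162 (se 0.0010), c = -0.213 (se 0.063)
#>   wave 3 (8-h): A = 0.0895 (se 0.0009), c = 1.666 (se 0.011)
#>   AR(1) rho = 0.306; SDs: pen 0.0116, dayf 0.0159, residual 0.025

daily_total(fit, 21)   # back-transformed L per pig on day 21
#> [1] 5.16

sens <- split_sensors(sim, cfg, seed = 3)
paired_location_test(location_means(sens), "water")$mean_diff
#> [1] 0.081  (F minus OF, L/pig/hour; p = 3.1e-05)
```

Reading the output: the initial mean and trend are on the square-root scale
(sqrt(L/pig/h)); the 24-h wave dominates the diurnal pattern with its
acrophase in the afternoon (hourly water peaks at 15:00, minimum at night);
`daily_total()` squares and sums the 24 hourly means — about 5 L per pig and
day three weeks into the finisher period; and the pens draw roughly
0.08 L/pig/h more from the cup beside the feeder than from the opposite one.

The whole chain (simulate → ingest → clean → all four analyses → CSV tables
and a Markdown report) runs as one call:

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "out")
```

or from the shell via the bundled CLI:

```sh
Rscript inst/cli/pigflow.R run-all --seed 1 --out-dir out
```

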
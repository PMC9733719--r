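---
title: "Modelling drinker use in finisher pig pens: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drinker use in finisher pig pens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Commercial finisher pens are typically fitted with two drinking cups whose
water flow can be metered cheaply at high resolution. Hourly water use and
drinker activations per pig carry information about age, diurnal activity,
resource competition (stocking density), cup preference, and - potentially -
impending welfare events such as tail biting. `pigflow` implements the full
analysis chain for such data: flow-meter calibration and ingestion, outlier
cleaning, harmonic (cosinor) mixed modelling of the diurnal pattern and age
trend, time-period treatment analysis, paired cup-location comparison, and a
matched case-control analysis around tail-damage events. Because no public
dataset of this kind is deposited, the package ships a first-class synthetic
generator that emulates the statistical structure such studies assume, with
ground-truth labels for every mechanism.

## The core model

Let $y_{pdt}$ be a pen's hourly water use (L/pig/hour) or activation
frequency (no/pig/hour) on study day $d$ at clock hour $t \in \{0,\dots,23\}$
(hour start). On the square-root scale the diurnal/age-trend model is

$$\sqrt{y_{pdt}} = \mu_0 + \beta d
  + \sum_{i=1}^{3} (A_i + \delta_i d)\,\sin(b_i t + c_i)
  + u_p + v_{pd} + \varepsilon_{pdt},$$

with fixed angular frequencies $b_i = i\cdot 2\pi/24$ (24-, 12- and 8-hour
cycles), amplitudes $A_i$ and phases $c_i$ estimated, random intercepts for
pen ($u_p$) and day-within-pen ($v_{pd}$), and AR(1)-correlated hourly
residuals within each pen-day. Estimation linearizes each wave as
$A\sin(bt+c) = u\,\sin(bt) + v\,\cos(bt)$, so the fixed effects are linear;
amplitude/phase are derived as $A = \sqrt{u^2+v^2}$, $c = \operatorname{atan2}(v,u)$
with delta-method standard errors. The canonical form has $A \ge 0$ and
$c \in (-\pi, \pi]$; a negative printed amplitude is the same wave with its
phase shifted by $\pi$. Back-transformation of any estimate is squaring (no
smearing correction): the clipped square of the sqrt-scale mean is reported
as the expected curve.

The square-root transform stabilises the strong mean-variance coupling of
non-negative hourly totals; it also means a Gaussian draw can be negative, so
the generator clips at zero before squaring. The default variance components
are deliberately small (see below) precisely so that this guard is
essentially never active and the generator stays faithful to the plain
Gaussian model the analysis assumes.

## Tunable parameters and defaults

* Fixed effects (`generator_config()$water`, `$activations`): the published
  square-root-scale estimates - water $\mu_0 = 0.343$, $\beta = 0.003214$,
  $A = (0.275, -0.0171, 0.0896)$, $c = (-1.84, 2.90, 1.67)$; activations
  $\mu_0 = 1.31$, $\beta = 0.000967$, $A = (0.82, 0.045, 0.27)$,
  $c = (-1.86, 2.82, 1.59)$. Units: sqrt(L/pig/h) and sqrt(no/pig/h);
  $t$ is hour-of-day at hour start (the phase convention was verified by
  checking that the predicted water maximum lands at 15:00, inside the
  12:00-17:59 peak period, and the minimum at night).
* Day-by-wave interactions $\delta_i$ exist in the model but are not
  published; the generator defaults them to zero (configurable).
* Variance components and the AR(1) coefficient are not published.
  Defaults (sqrt scale): water pen SD 0.010, day-within-pen SD 0.015,
  residual SD 0.025, $\rho = 0.3$; activations 0.040/0.050/0.080, $\rho=0.3$.
  These are invented and documented as such. They were chosen small, for two
  reasons: the reference analysis assumes an untruncated Gaussian on the
  sqrt scale, and the water mean function dips to ~0.054 on early-study
  nights - larger noise would make the zero-clipping guard bite and bias
  recovery. Parameter-recovery checks hold across +/-50% perturbations of
  these defaults.
* Time periods (`assign_period()`): Peak1 06:00-11:59, Peak2 12:00-17:59,
  Low 18:00-05:59. Week is `floor((day-1)/7) + 1`; the period model centres
  week so intercepts are week-1 values.
* Stocking-density effects: per-period back-transformed low-minus-high
  differences (defaults 0.056 L/pig/h in Peak2 for water; 0.55 and 0.91
  no/pig/h in Peak1/Peak2 for activations) are applied symmetrically on the
  sqrt scale, low $+d/2$ and high $-d/2$ with $d = \Delta/(2m)$ anchored at
  the week-5 period mean $m$. Symmetric application keeps the stock-marginal
  period intercepts equal to the configured week-1 values and makes the
  back-transformed marginal contrast exactly $2md = \Delta$.
* Tail-damage events: constant per-pen-day hazard, default solving
  $1-(1-h)^{63} = 54/110$ (the realized event scale of the reference study);
  at most one event per pen, and the pen exits the study at its event.
  Case offsets are one-sided (case = control + $d$ on the sqrt scale,
  $d = \sqrt{m^2+\Delta} - m$ at the day-31 period mean), applied on **all**
  days of the case pen - the reference analysis found case-control
  differences independent of day relative to the event.
* The Low-period case offset default is the *share-preserving* value
  $\delta_{\text{Low}} = L(\Delta_1+\Delta_2)/(P_1+P_2)$ (back-transformed
  day-31 period means $L, P_1, P_2$). This resolves an internal tension in
  the reported results: peak-only additive offsets would necessarily depress
  the Low-period share, while the study reports that share as unaffected by
  pen type, and reports the Low contrast itself only as non-significant (not
  as zero). The derived default (~0.009 L/pig/h) satisfies all three
  printed facts simultaneously.
* Drinker-location preference: each pen draws its feeder-side (F) share from
  a beta distribution (mean ~0.653, SD 0.08) and re-draws it with
  probability 0.02 per day (preference switching is observed in real pens).
  The default mean share is calibrated analytically so that the expected
  paired F-OF water difference equals the published 0.075 L/pig/h at the
  generator's own mean level, $s = 1/2 + 0.075/(2\,E[\text{water}])$. The
  published raw per-cup means (0.179/0.104) sum to more water than the
  published model-based mean function implies, so the difference - the
  quantity the paired test addresses - was given priority; the simulated
  F and OF levels land proportionally below the raw table.
* Sensor anomalies: stuck nipple (2 L/pig/h, one activation), slow leak
  (0.01 L/pig/h), dropout (all zero), at a default rate of 0.5% of
  sensor-hours - the deletion fraction the reference cleaning reported for
  water.

## Cleaning

Cleaning fits, separately per batch and per response, a fixed-effects OLS
model of the sqrt-scale response on day, three harmonic pairs and their
day interactions, and discards observation hours deviating strictly more
than `k = 4` residual SDs from their fitted values, in a single pass
(fit once, flag once) and independently per response, so the water and
activation masks differ. Two deliberate consequences are worth knowing:

* The OLS residual SD on clean data is the *total* sqrt-scale SD
  (pen + day + hourly residual), not the AR(1) innovation SD. "Gross"
  anomalies in the tests are therefore defined relative to that total SD.
* Contamination inflates the residual SD before flagging (at a 0.5-0.8%
  anomaly rate with large stuck-flow values the SD roughly doubles), so
  faults barely past the 8-SD line can be missed. This is a property of any
  single-pass SD rule; the reference procedure was also single-pass, so no
  re-fitting iteration is performed. Recall on faults well past the line
  is ~100%; false positives on clean Gaussian data are at the 4-SD normal
  tail (~0.006%).

The cleaning model operates on the sqrt scale. The reference text states the
transform for the inferential models and is silent for cleaning; sqrt was
chosen for consistency and variance stabilisation, and `sqrt_scale = FALSE`
is provided as the documented switch.

## Mixed-model estimation

All three inferential models (`fit_harmonic_mixed()`, `fit_period_model()`,
`fit_event_model()`) are Gaussian linear mixed models estimated by REML with
`nlme::lme` and an AR(1) correlation structure; backward elimination uses ML
likelihood-ratio tests between nested fits (marginality respected, ties
broken by largest p, then lexicographic term order, making elimination
invariant to row order), followed by a REML refit of the retained structure.

Two adaptations to the reference specification were required by the
estimation engine:

* The period model's random structure is stated as an intercept per period
  nested within week, pen and batch. An AR(1) over the gapped hour index
  inside week-by-period groups is numerically singular in `nlme`, and the
  correlation grouping must nest inside the innermost random level. The
  model therefore uses random intercepts for day-within-pen(-within-batch)
  with AR(1) across hours within a pen-day - exactly the dependence
  structure the synthetic generator states - which leaves fixed effects
  unchanged on balanced designs.
* Optimizer cascade: `nlminb`, then Nelder-Mead `optim`, and as a last
  resort the continuous-time `corCAR1` (identical to AR(1) on an integer
  hour lattice for positive correlation) accepting boundary convergence,
  always with a warning. Non-convergence is never silent.

A documented OLS fixed-effect fallback (`method = "ols"`) exists for the
harmonic model: on balanced designs it reproduces the mixed fixed effects,
and it is the exact route for noise-free input, where REML is degenerate.
Its SEs are naive and it reports no variance components.

At the matched-pair scale (23 pairs, 552 rows for the mean statistic) the
event model's REML variance components are boundary-prone and its
delta-method SEs understate replicate-to-replicate variability by roughly
50%. The acceptance tests therefore calibrate recovery against empirical
SEs across 20 seeded replicates rather than against single-fit SEs.

## Nonparametric comparisons

Low-period shares (per pen for the stocking comparison, n = 56; per pen-day
for the event comparison, 92 per pen type and 46 per day offset, matching the
reported group sizes) use the Mann-Whitney U test, exact when both groups
have at most 25 observations and no ties, otherwise the normal approximation
with continuity and tie correction. The cup-location comparison aggregates to
one observation per pen per location and uses the paired Wilcoxon signed-rank
test with zero differences dropped, exact for at most 25 non-zero untied
pairs. No multiplicity correction is applied across the batch and
stocking-density subset tests (none was applied in the reference analysis);
this is a reporting convention, not a recommendation.

A note on the printed share percentages: the published week-1 period
intercepts and slopes imply a Low-period share of roughly 16-17%, whereas
the published raw-data shares are 24-27%. The generator follows the printed
model parameters, so its shares sit near 16%; the *direction* (high-stocking
pens shift a larger share of use into the Low period) is reproduced and is
what the share test asserts.

## Matched-pair construction

Each tail-damage pen is paired with a control from the same batch with
identical treatment levels. Controls are drawn from the never-damaged pool
(`clear_after = Inf`): the per-combination pair counts of the reference
study are bounded by its never-damaged counts, which the weaker
"event-free for one week after day 0" clause cannot reproduce; that weaker
clause remains available (`clear_after = 7`). Proximity is the absolute
difference of room position indices, ties to the lower index. Controls may
be reused across events (reuse is flagged and enters the model through the
event-level random intercept). Events whose day -3..0 window precedes the
study start, or with no eligible control, are dropped with a logged reason.
"Age at day 0" enters as the study day of the event (true ages are not
available in pen-level data).

## What a green test does and does not establish

The generator reproduces the *model* the reference analysis assumes -
sqrt-scale Gaussian data with a three-wave diurnal mean, linear age trend,
pen/day intercepts and within-day AR(1) - with effects injected exactly
where the analysis looks for them. Green recovery tests therefore establish
that the pipeline is a correct estimator of that world at the study's scale.
They do not establish anything about phenomena the generator does not
contain: real drinking is bursty and zero-inflated at the bout level,
diurnal shape varies with season, temperature and feeding schedule, sensor
faults drift rather than switch, day-by-wave amplitude interactions are
non-zero in real data (the published daily totals of 3.7-8.2 L/pig/day
depend on them and are deliberately not acceptance targets), and treatment
effects need not be additive on the sqrt scale. Real-data chi-square
statistics and p-values are likewise out of reach by construction.

## Numerical conventions

* Hour coordinate: integer hour of day at hour start; phases in radians.
* Flow events are counted, with all their pulses, in the hour of their
  start record (boundary-spanning bouts are not split).
* Hours with no flow are explicit zero rows (the AR(1) lattice needs them).
* Daily totals from a fit sum the 24 back-transformed hourly means; the
  optional variance correction adds the total sqrt-scale variance per hour
  before summation and is off by default. On the 24-hour lattice the waves
  are orthogonal and sum to zero, so (absent clipping) the closed form is
  $24\mu_d^2 + 12\sum_i A_i^2$.
* Pulse emission quantizes water to `round(L x pulses_per_liter)` and
  activations to whole bouts; the emitted quantized table, not the raw
  continuous one, is the round-trip invariant of `aggregate_hourly()`.
* Seeds: every stochastic function takes a `seed` and restores the caller's
  RNG state; a fixed seed fixes outputs byte for byte.
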
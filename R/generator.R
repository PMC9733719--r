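#' Synthetic-study generator configuration
#'
#' Bundles every tunable of the synthetic drinker-use generator. Defaults for
#' the fixed effects are the published square-root-scale estimates of the
#' diurnal/age-trend model (initial mean, daily trend, and three harmonic
#' waves with 24/12/8-hour cycles) for both responses, water use (L/pig/hour)
#' and drinker activations (no/pig/hour). Variance components and the AR(1)
#' coefficient are not published; the documented defaults are deliberately
#' small so that the Gaussian sqrt-scale model is effectively untruncated by
#' the >= 0 clipping guard (see the methods vignette).
#'
#' @param study_days length of the study in days (default 63 = 9 weeks).
#' @param water,activations lists of per-response parameters: `mu0`
#'   (sqrt-scale initial mean), `trend` (sqrt-scale change per day), `amp`
#'   and `phase` (length-3 amplitude/phase of the three waves; angular
#'   frequencies are fixed at i*2*pi/24), `delta` (day-by-wave amplitude
#'   trends, default 0), `pen_sd`, `day_sd`, `resid_sd` (sqrt-scale SDs of
#'   the pen intercept, day-within-pen intercept and hourly residual) and
#'   `rho` (AR(1) coefficient of adjacent hourly residuals within a day).
#' @param period per-response time-period parameters used by the period-mode
#'   generator: sqrt-scale week-1 `intercepts` and weekly `slopes` for
#'   (Low, Peak1, Peak2), back-transformed low-minus-high stocking
#'   differences `stock_diff_bt`, and the `baseline_week` at which those
#'   differences are anchored.
#' @param preference drinker-location split: `f_share_mean` (expected share
#'   of pen use taken at the feeder-side cup; default calibrated so the mean
#'   paired F-OF water difference equals the published 0.075 L/pig/hour at
#'   the generator's own mean level), `f_share_sd` (between-pen SD of the
#'   share), `switch_prob` (per-day probability that a pen re-draws its
#'   preference).
#' @param anomaly sensor-fault injection: `rate` (per sensor-hour), `weights`
#'   for the three fault types (stuck nipple, slow leak, dropout),
#'   `stuck_water` and `leak_water` (L/pig/hour values imposed).
#' @param events tail-damage process: per-pen-day `hazard` (default solves
#'   1-(1-h)^63 = 54/110, the realized event scale of the study),
#'   back-transformed per-period case offsets `effect_water_bt` /
#'   `effect_act_bt`, and the `baseline_day` anchoring their sqrt-scale
#'   shifts.
#' @param pulses_per_liter nominal flow-meter resolution used when emitting
#'   pulse-level streams.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(study_days = 63,
                             water = list(),
                             activations = list(),
                             period = list(),
                             preference = list(),
                             anomaly = list(),
                             events = list(),
                             pulses_per_liter = 1000) {
  def_water <- list(mu0 = 0.343, trend = 0.003214,
                    amp = c(0.275, -0.0171, 0.0896),
                    phase = c(-1.84, 2.90, 1.67),
                    delta = c(0, 0, 0),
                    pen_sd = 0.010, day_sd = 0.015, resid_sd = 0.025,
                    rho = 0.3)
  def_act <- list(mu0 = 1.31, trend = 0.000967,
                  amp = c(0.82, 0.045, 0.27),
                  phase = c(-1.86, 2.82, 1.59),
                  delta = c(0, 0, 0),
                  pen_sd = 0.040, day_sd = 0.050, resid_sd = 0.080,
                  rho = 0.3)
  ## Week-1 period intercepts/slopes on the sqrt scale; intercepts are the
  ## sqrt of the published back-transformed week-1 values.
  def_period <- list(
    water = list(intercepts = sqrt(c(Low = 0.047, Peak1 = 0.205, Peak2 = 0.304)),
                 slopes = c(Low = 0.015, Peak1 = 0.032, Peak2 = 0.029),
                 stock_diff_bt = c(Low = 0, Peak1 = 0, Peak2 = 0.056)),
    activations = list(intercepts = sqrt(c(Low = 0.58, Peak1 = 2.58, Peak2 = 3.66)),
                       slopes = c(Low = 0.0099, Peak1 = 0.017, Peak2 = -0.0011),
                       stock_diff_bt = c(Low = 0, Peak1 = 0.55, Peak2 = 0.91)),
    baseline_week = 5)
  def_pref <- list(f_share_mean = NULL, f_share_sd = 0.08, switch_prob = 0.02)
  def_anom <- list(rate = 0.005,
                   weights = c(stuck = 0.4, leak = 0.3, dropout = 0.3),
                   stuck_water = 2.0, leak_water = 0.01)
  def_events <- list(hazard = 1 - (1 - 54 / 110)^(1 / 63),
                     effect_water_bt = c(Low = NA, Peak1 = 0.041, Peak2 = 0.058),
                     effect_act_bt = c(Low = NA, Peak1 = 0.34, Peak2 = 0.47),
                     baseline_day = 31)

  cfg <- list(
    study_days = study_days,
    water = utils::modifyList(def_water, water),
    activations = utils::modifyList(def_act, activations),
    period = utils::modifyList(def_period, period),
    preference = utils::modifyList(def_pref, preference),
    anomaly = utils::modifyList(def_anom, anomaly),
    events = utils::modifyList(def_events, events),
    pulses_per_liter = pulses_per_liter
  )
  ## A Low-period case offset of NA (the default) asks for the
  ## share-preserving value: the study reports higher case use in the two
  ## peaks AND Low-period shares unaffected by pen type, which is only
  ## consistent if Low use rises proportionally. Solving share equality gives
  ## delta_Low = L (D1 + D2) / (P1 + P2) with L, P1, P2 the back-transformed
  ## period means on the baseline day and D1, D2 the peak offsets.
  for (resp in c("water", "activations")) {
    fld <- if (resp == "water") "effect_water_bt" else "effect_act_bt"
    eff <- cfg$events[[fld]]
    if (is.na(eff[["Low"]])) {
      pm <- period_bt_means(cfg, resp, cfg$events$baseline_day)
      eff[["Low"]] <- pm[["Low"]] * (eff[["Peak1"]] + eff[["Peak2"]]) /
        (pm[["Peak1"]] + pm[["Peak2"]])
      cfg$events[[fld]] <- eff
    }
  }
  if (is.null(cfg$preference$f_share_mean)) {
    ## Calibrate the feeder-side share so the expected paired F-OF water
    ## difference equals 0.075 L/pig/hour at this config's mean level:
    ## E[F - OF] = (2s - 1) E[water].
    m <- mean_hourly_level(cfg, "water")
    cfg$preference$f_share_mean <- 0.5 + 0.075 / (2 * m)
  }
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

## Back-transformed mean level per time period on one day (harmonic mode).
period_bt_means <- function(cfg, response, day) {
  p <- cfg[[response]]
  vapply(period_levels, function(pl) {
    hrs <- (0:23)[as.character(assign_period(0:23)) == pl]
    mean(harmonic_sqrt_mean(day, hrs, p)^2)
  }, numeric(1))
}

## Analytic expected hourly back-transformed level under the harmonic mode:
## E[x^2] = mean over days/hours of m(d,t)^2 plus all variance components.
mean_hourly_level <- function(cfg, response) {
  p <- cfg[[response]]
  grid <- expand.grid(hour = 0:23, day = seq_len(cfg$study_days))
  m <- harmonic_sqrt_mean(grid$day, grid$hour, p)
  mean(m^2) + p$pen_sd^2 + p$day_sd^2 + p$resid_sd^2
}

validate_generator_config <- function(cfg) {
  bad <- function(field, msg) pf_stop("invalid generator config field '", field, "': ", msg)
  if (!(is.numeric(cfg$study_days) && cfg$study_days >= 1)) bad("study_days", "must be >= 1")
  for (r in c("water", "activations")) {
    p <- cfg[[r]]
    for (f in c("pen_sd", "day_sd", "resid_sd"))
      if (p[[f]] < 0) bad(paste0(r, "$", f), "SD must be >= 0")
    if (abs(p$rho) >= 1) bad(paste0(r, "$rho"), "must satisfy |rho| < 1")
    if (length(p$amp) != 3 || length(p$phase) != 3 || length(p$delta) != 3)
      bad(r, "amp, phase and delta must have length 3")
  }
  pr <- cfg$preference
  if (!(pr$f_share_mean > 0 && pr$f_share_mean <= 1))
    bad("preference$f_share_mean", "must lie in (0, 1]")
  if (pr$f_share_mean == 1 && pr$f_share_sd > 0)
    bad("preference$f_share_sd", "must be 0 when the share is fixed at 1")
  if (pr$f_share_sd < 0) bad("preference$f_share_sd", "must be >= 0")
  if (pr$switch_prob < 0 || pr$switch_prob > 1)
    bad("preference$switch_prob", "must lie in [0, 1]")
  if (cfg$anomaly$rate < 0 || cfg$anomaly$rate > 1)
    bad("anomaly$rate", "must lie in [0, 1]")
  if (any(cfg$anomaly$weights < 0)) bad("anomaly$weights", "must be >= 0")
  if (cfg$events$hazard < 0 || cfg$events$hazard > 1)
    bad("events$hazard", "must lie in [0, 1]")
  if (cfg$pulses_per_liter <= 0) bad("pulses_per_liter", "must be > 0")
  invisible(cfg)
}

## Sqrt-scale harmonic mean function m(day, hour): mu0 + trend*day +
## sum_i (A_i + delta_i*day) sin(b_i*hour + c_i), b_i = i*2*pi/24,
## hour evaluated at hour start (0..23).
harmonic_sqrt_mean <- function(day, hour, p) {
  m <- p$mu0 + p$trend * day
  for (i in 1:3)
    m <- m + (p$amp[i] + p$delta[i] * day) * sin(i * 2 * pi / 24 * hour + p$phase[i])
  m
}

## Sqrt-scale period-mode mean: week-1 intercept + weekly slope, with the
## symmetric stocking shift (low +d/2, high -d/2) anchored at baseline_week.
period_sqrt_mean <- function(day, hour, pp, stock, baseline_week) {
  per <- as.character(assign_period(hour))
  week <- (day - 1) %/% 7 + 1
  m <- pp$intercepts[per] + pp$slopes[per] * (week - 1)
  m_base <- pp$intercepts + pp$slopes * (baseline_week - 1)
  d <- sqrt_shift_symmetric(pp$stock_diff_bt, m_base)[per]
  unname(m + ifelse(stock == "low", d / 2, -d / 2))
}
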
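# shared fixtures: everything is generated in code at test time

## published sqrt-scale fixed effects (the generator defaults)
tbl2 <- list(
  water = list(mu0 = 0.343, trend = 0.003214,
               amp = c(0.275, -0.0171, 0.0896), phase = c(-1.84, 2.90, 1.67)),
  act = list(mu0 = 1.31, trend = 0.000967,
             amp = c(0.82, 0.045, 0.27), phase = c(-1.86, 2.82, 1.59))
)

## a generator with all randomness switched off (the pure mean function)
noise_free_config <- function(study_days = 10, ...) {
  generator_config(
    study_days = study_days,
    water = list(pen_sd = 0, day_sd = 0, resid_sd = 0, rho = 0),
    activations = list(pen_sd = 0, day_sd = 0, resid_sd = 0, rho = 0),
    ...)
}

quick_config <- function(study_days = 14, ...) generator_config(study_days = study_days, ...)

small_sim <- function(n_per_combination = 2, study_days = 14, seed = 1,
                      config = quick_config(study_days), mode = "harmonic") {
  roster <- generate_pen_roster(n_per_combination, 1, seed = seed)
  simulate_pen_hourly(roster, config, seed = seed + 1000L, mode = mode)
}

## manual sqrt-scale mean function, written independently of the generator
oracle_mean <- function(day, hour, p) {
  m <- p$mu0 + p$trend * day
  b <- (1:3) * 2 * pi / 24
  for (i in 1:3) m <- m + p$amp[i] * sin(b[i] * hour + p$phase[i])
  m
}

## a constant-rate hourly table for boundary/identity tests
flat_hourly <- function(pens = c("A", "B"), days = 2, value = 0.2, act = 1,
                        batch = 1) {
  g <- expand.grid(hour = 0:23, day = seq_len(days), pen_id = pens,
                   stringsAsFactors = FALSE)
  data.frame(pen_id = g$pen_id, batch = batch, day = g$day, hour = g$hour,
             n_pigs = 11L, water = value, activations = act,
             stringsAsFactors = FALSE)
}

expect_within <- function(est, target, tol) {
  expect_lt(abs(est - target), tol)
}
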
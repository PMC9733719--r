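test_that("harmonic design columns are the wave linearization", {
  rows <- data.frame(day = c(1, 10), hour = c(0, 6))
  X <- build_harmonic_design(rows)
  expect_equal(ncol(X), 14)
  expect_equal(unname(X[1, c("sin1", "sin2", "sin3")]), c(0, 0, 0))
  expect_equal(unname(X[1, c("cos1", "cos2", "cos3")]), c(1, 1, 1))
  expect_equal(unname(X[2, "sin1"]), 1) # sin(pi/2)
  g <- data.frame(day = 1, hour = 0:23)
  Xg <- build_harmonic_design(g)
  for (i in 1:3)
    expect_equal(Xg[, paste0("sin", i)]^2 + Xg[, paste0("cos", i)]^2, rep(1, 24))
  expect_error(build_harmonic_design(rows, n_waves = 0), "n_waves")
})

test_that("amplitude/phase conversion is canonical and invertible", {
  ap <- amplitude_phase(0, 1)
  expect_equal(ap$A, 1)
  expect_equal(ap$c, pi / 2)

  ## published wave-1 water pair, derived by direct trigonometry
  uv <- phase_coeffs(0.275, -1.84)
  expect_equal(uv$u, -0.07314007, tolerance = 1e-7)
  expect_equal(uv$v, -0.26509531, tolerance = 1e-7)
  back <- amplitude_phase(uv$u, uv$v)
  expect_equal(back$A, 0.275)
  expect_equal(back$c, -1.84)

  ## property: round trip over a deterministic grid, including negatives
  set.seed(1)
  for (i in 1:50) {
    u <- runif(1, -2, 2); v <- runif(1, -2, 2)
    ap <- amplitude_phase(u, v)
    uv2 <- phase_coeffs(ap$A, ap$c)
    expect_equal(c(uv2$u, uv2$v), c(u, v), tolerance = 1e-12)
    expect_gte(ap$A, 0)
    expect_true(ap$c > -pi && ap$c <= pi)
  }
  expect_equal(amplitude_phase(0, 0), list(A = 0, c = 0))
  ## negative printed amplitudes map to the same wave in canonical form
  cw <- canonical_wave(-0.0171, 2.90)
  expect_equal(cw$A, 0.0171)
  expect_equal(cw$c, 2.90 - pi)
})

test_that("noise-free input is fit exactly through the OLS route", {
  s0 <- small_sim(n_per_combination = 2, study_days = 10, seed = 2,
                  config = noise_free_config(10))
  fit <- fit_harmonic_mixed(s0, "water")
  expect_equal(fit$method, "ols")
  expect_equal(fit$mu0, 0.343, tolerance = 1e-9)
  expect_equal(fit$trend, 0.003214, tolerance = 1e-9)
  expect_equal(fit$waves$A[1], 0.275, tolerance = 1e-9)
  expect_equal(fit$waves$c[1], -1.84, tolerance = 1e-9)
  ## wave 2 was printed with a negative amplitude; the fit is canonical
  expect_equal(fit$waves$A[2], 0.0171, tolerance = 1e-9)
  expect_equal(fit$waves$c[2], 2.90 - pi, tolerance = 1e-8)
})

test_that("mixed fit recovers generating parameters with honest SEs", {
  s <- small_sim(n_per_combination = 2, study_days = 21, seed = 3)
  fit <- fit_harmonic_mixed(s, "water")
  expect_equal(fit$method, "lme")
  expect_true(fit$converged)
  expect_within(fit$mu0, 0.343, 4 * fit$se["(Intercept)"])
  expect_within(fit$trend, 0.003214, 4 * fit$se["day"])
  expect_within(fit$waves$A[1], 0.275, 4 * fit$waves$se_A[1])
  expect_within(fit$waves$c[1], -1.84, 4 * fit$waves$se_c[1])
  ## invented variance components are recovered to the right order
  expect_within(fit$varcomp[["residual"]], 0.025, 0.004)
  expect_within(fit$rho, 0.3, 0.1)

  ## null AR(1): estimated rho near zero
  s0 <- small_sim(n_per_combination = 2, study_days = 14, seed = 4,
                  config = generator_config(study_days = 14,
                                            water = list(rho = 0)))
  f0 <- fit_harmonic_mixed(s0, "water")
  expect_lt(abs(f0$rho), 0.05)
})

test_that("estimator precision improves with pen count", {
  ## fixed-effect route (identical point estimates on balanced designs)
  err <- function(n_per, seeds) vapply(seeds, function(s) {
    d <- small_sim(n_per_combination = n_per, study_days = 14, seed = 100 + s)
    abs(fit_harmonic_mixed(d, "water", method = "ols")$mu0 - 0.343)
  }, numeric(1))
  rmse8 <- sqrt(mean(err(1, 1:8)^2))
  rmse32 <- sqrt(mean(err(4, 1:8)^2))
  expect_lt(rmse32, rmse8)
})

test_that("diurnal prediction and daily totals match closed forms", {
  flat <- generator_config(study_days = 5,
                           water = list(mu0 = 0.5, trend = 0, amp = c(0, 0, 0),
                                        pen_sd = 0, day_sd = 0, resid_sd = 0),
                           activations = list(pen_sd = 0, day_sd = 0, resid_sd = 0))
  sf <- simulate_pen_hourly(generate_pen_roster(1, 1, seed = 5), flat, seed = 6)
  ff <- fit_harmonic_mixed(sf, "water")
  pd <- predict_diurnal(ff, 3)
  expect_equal(pd$expected, rep(0.25, 24), tolerance = 1e-9)
  expect_equal(daily_total(ff, 3), 6, tolerance = 1e-8)

  s0 <- small_sim(n_per_combination = 1, study_days = 40, seed = 7,
                  config = noise_free_config(40))
  fit0 <- fit_harmonic_mixed(s0, "water")
  pd31 <- predict_diurnal(fit0, 31)
  expect_equal(pd31$expected[pd31$hour == 13], 0.4430430, tolerance = 1e-6)
  expect_equal(pd31$hour[which.max(pd31$expected)], 15)
  expect_equal(pd31$hour[which.min(pd31$expected)], 3)

  ## closed form: 24 mu_day^2 + 12 sum(A_i^2) (cross terms cancel on the lattice)
  mu31 <- 0.343 + 0.003214 * 31
  expect_equal(daily_total(fit0, 31), 24 * mu31^2 + 12 * sum(tbl2$water$amp^2),
               tolerance = 1e-6)
  expect_equal(daily_total(fit0, 31), 5.709543, tolerance = 1e-6)

  ## monotone in day when the trend is positive and deltas are zero
  tots <- vapply(1:40, function(d) daily_total(fit0, d), numeric(1))
  expect_true(all(diff(tots) > 0))
  expect_warning(predict_diurnal(fit0, 99), "outside the fitted range")

  ## 24-hour lattice sum of each wave is zero for any phase
  set.seed(8)
  for (i in 1:3) for (ph in runif(3, -pi, pi))
    expect_equal(sum(sin(i * 2 * pi / 24 * (0:23) + ph)), 0, tolerance = 1e-12)
})
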
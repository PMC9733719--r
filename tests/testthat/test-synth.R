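test_that("pen roster is balanced, positioned and deterministic", {
  r <- generate_pen_roster(1, 1, seed = 1)
  expect_equal(nrow(r), 8)
  expect_equal(nrow(unique(r[c("tail", "straw", "stock")])), 8)

  r3 <- generate_pen_roster(4, 3, seed = 2)
  expect_equal(nrow(r3), 3 * 8 * 4)
  counts <- table(r3$batch, interaction(r3$tail, r3$straw, r3$stock))
  expect_true(all(counts == 4))
  expect_true(all(tapply(r3$position, r3$batch, anyDuplicated) == 0))
  expect_true(all((r3$stock == "high") == (r3$n_pigs == 18)))
  expect_true(all((r3$stock == "low") == (r3$n_pigs == 11)))

  expect_identical(generate_pen_roster(3, 2, seed = 9),
                   generate_pen_roster(3, 2, seed = 9))
  expect_error(generate_pen_roster(0, 1), "positive")
  expect_error(generate_pen_roster(2, -1), "positive")

  rs <- roster_study_scale(seed = 3)
  expect_equal(nrow(rs), 112)
  expect_equal(as.vector(table(rs$batch)), c(32L, 16L, 32L, 32L))
  ## reduced batch 2: 3 pens per docked combination, 1 per undocked
  b2 <- rs[rs$batch == 2, ]
  expect_equal(as.vector(table(b2$tail)), c(12L, 4L))
})

test_that("simulated hourly values follow the configured mean function", {
  r <- generate_pen_roster(1, 1, seed = 4)
  ## flat world: constant mu0, no waves, no noise
  flat <- generator_config(study_days = 3,
                           water = list(mu0 = 0.343, trend = 0, amp = c(0, 0, 0),
                                        pen_sd = 0, day_sd = 0, resid_sd = 0))
  s <- simulate_pen_hourly(r, flat, seed = 5)
  expect_equal(unique(s$water), 0.343^2)

  ## full mean function, zero variance: direct trigonometric evaluation
  cfg0 <- noise_free_config(study_days = 31)
  s0 <- simulate_pen_hourly(r, cfg0, seed = 6)
  expect_equal(s0$water[s0$day == 31 & s0$hour == 13][1], 0.4430430,
               tolerance = 1e-6)
  expect_equal(s0$water, oracle_mean(s0$day, s0$hour, tbl2$water)^2,
               tolerance = 1e-12)
  expect_equal(s0$activations, oracle_mean(s0$day, s0$hour, tbl2$act)^2,
               tolerance = 1e-12)
  expect_true(all(s0$water >= 0) && all(s0$activations >= 0))

  ## deterministic diurnal extremes fall in the documented windows
  d31 <- s0[s0$day == 31, ]
  hmin <- d31$hour[which.min(d31$water)]
  hmax <- d31$hour[which.max(d31$water)]
  expect_true(hmin >= 18 || hmin <= 5)
  expect_true(hmax >= 12 && hmax <= 17)

  ## law of large numbers: sample mean of sqrt values at a fixed (day, hour)
  big <- generate_pen_roster(25, 1, seed = 7) # 200 pens
  cfgn <- quick_config(study_days = 2)
  sn <- simulate_pen_hourly(big, cfgn, seed = 8)
  at <- sn$water[sn$day == 2 & sn$hour == 13]
  m <- oracle_mean(2, 13, tbl2$water)
  tot_sd <- sqrt(0.010^2 + 0.015^2 + 0.025^2)
  expect_within(mean(sqrt(at)), m, 4 * tot_sd / sqrt(length(at)))

  ## fixed seed fixes everything byte for byte
  expect_identical(simulate_pen_hourly(r, cfgn, seed = 9),
                   simulate_pen_hourly(r, cfgn, seed = 9))
  expect_error(simulate_pen_hourly(r, generator_config(water = list(resid_sd = -1))),
               "resid_sd")
})

test_that("sensor split conserves pen totals and honors the preference share", {
  s <- small_sim(seed = 10)
  cfg <- quick_config()
  sens <- split_sensors(s, cfg, seed = 11)
  pen <- pen_level(sens)
  key <- function(d) paste(d$pen_id, d$day, d$hour)
  i <- match(key(pen), key(s))
  expect_equal(pen$water, s$water[i], tolerance = 0)
  expect_equal(pen$activations, s$activations[i], tolerance = 0)

  ## share fixed at 1 -> everything on the feeder-side cup
  cfg1 <- quick_config(preference = list(f_share_mean = 1, f_share_sd = 0))
  sens1 <- split_sensors(s, cfg1, seed = 12)
  expect_true(all(sens1$water[sens1$location == "OF"] == 0))

  ## defaults reproduce the published paired F-OF water difference
  r56 <- generate_pen_roster(7, 1, seed = 13)
  cfg63 <- generator_config()
  s63 <- simulate_pen_hourly(r56, cfg63, seed = 14)
  sens63 <- split_sensors(s63, cfg63, seed = 15)
  lm63 <- location_means(sens63)
  expect_within(mean(lm63$water_F - lm63$water_OF), 0.075, 0.012)
})

test_that("anomaly injection matches its rate and is recoverable", {
  s <- small_sim(seed = 16)
  cfg <- quick_config()
  sens <- split_sensors(s, cfg, seed = 17)

  cfg0 <- quick_config(anomaly = list(rate = 0))
  out0 <- inject_anomalies(sens, cfg0, seed = 18)
  expect_identical(out0$data, sens)
  expect_equal(nrow(out0$labels), 0)

  out <- inject_anomalies(sens, cfg, seed = 19)
  n <- nrow(sens); p <- 0.005
  expect_within(nrow(out$labels) / n, p, 4 * sqrt(p * (1 - p) / n))
  ## stuck faults sit far above any fitted sqrt-scale value
  stuck <- out$labels[out$labels$type == "stuck", ]
  expect_true(all(sqrt(cfg$anomaly$stuck_water) -
                    sqrt(stuck$water_orig) > 8 * 0.025))
  expect_error(inject_anomalies(sens, quick_config(anomaly = list(rate = 2))),
               "rate")
})

test_that("tail-damage events censor pens and carry the configured offsets", {
  r <- roster_study_scale(seed = 20)
  cfg <- generator_config()
  expect_equal(nrow(schedule_tail_events(r, generator_config(events = list(hazard = 0)),
                                         seed = 21)), 0)
  ## default hazard reproduces the realized event scale (~54 of 110-112 pens)
  n_ev <- sum(vapply(1:3, function(s)
    nrow(schedule_tail_events(r, cfg, seed = 21 + s)), numeric(1)))
  expect_within(n_ev / 3, 54 * 112 / 110, 3 * sqrt(112 * 0.49 * 0.51 / 3))

  ev <- schedule_tail_events(r, cfg, seed = 25)
  expect_lte(max(table(ev$pen_id)), 1) # at most one event per pen

  ## offsets: with zero variance the Peak-2 mean difference on the baseline
  ## day equals the configured back-transformed effect exactly
  cfg0 <- noise_free_config(study_days = 63)
  r1 <- generate_pen_roster(1, 1, seed = 26)
  base <- simulate_pen_hourly(r1, cfg0, seed = 27)
  evt <- data.frame(pen_id = r1$pen_id[1], event_day = 40L)
  shifted <- apply_event_effects(base, evt, cfg0)
  expect_equal(max(shifted$day[shifted$pen_id == r1$pen_id[1]]), 40)
  p2 <- function(d) d$day == 31 & d$hour >= 12 & d$hour < 18
  case31 <- shifted[p2(shifted) & shifted$pen_id == r1$pen_id[1], "water"]
  ctrl31 <- base[p2(base) & base$pen_id == r1$pen_id[1], "water"]
  expect_equal(mean(case31) - mean(ctrl31), 0.058, tolerance = 1e-10)
})

test_that("pulse streams decompose hours and respect hard limits", {
  one <- data.frame(pen_id = "A", location = "F", sensor_id = "A-F",
                    n_pigs = 1L, day = 1L, hour = 3L,
                    water = 2, activations = 4)
  ps <- emit_pulse_stream(one, pulses_per_liter = 1000, seed = 30)
  expect_equal(nrow(ps$events), 4)
  expect_equal(sum(ps$events$pulses), 2000)
  expect_true(all(format(ps$events$start, "%H") == "03"))
  expect_true(all(ps$events$stop >= ps$events$start))

  zero <- one; zero$water <- 0; zero$activations <- 0
  expect_equal(nrow(emit_pulse_stream(zero, 1000)$events), 0)

  toomany <- one; toomany$activations <- 3601
  expect_error(emit_pulse_stream(toomany, 1000), "3600")
  expect_error(emit_pulse_stream(one, 0), "pulses_per_liter")
})
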
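#' Simulate pen-level hourly drinker use
#'
#' Draws hourly water use and activation frequency for every pen in the
#' roster over the configured study length. On the square-root scale each
#' observation is mean function + pen intercept + day-within-pen intercept +
#' stationary AR(1) hourly residual, clipped at zero and squared back to the
#' observation scale. Two mean functions are available: `"harmonic"` (initial
#' mean + daily trend + three harmonic waves) and `"period"` (week-1
#' intercept + weekly slope per time period, with the configured stocking
#' shifts applied in the peaks).
#'
#' @param roster pen roster from [generate_pen_roster()].
#' @param config a [generator_config()].
#' @param seed optional integer seed; fixing it fixes the output exactly.
#' @param mode `"harmonic"` or `"period"` mean structure.
#' @return a `data.frame` (pen_id, batch, tail, straw, stock, n_pigs,
#'   position, day, hour, water, activations), ordered by pen, day, hour,
#'   with a `"truth"` attribute holding the sqrt-scale mean and realized
#'   random components per response (see [sim_truth()]).
#' @export
simulate_pen_hourly <- function(roster, config = generator_config(), seed = NULL,
                                mode = c("harmonic", "period")) {
  mode <- match.arg(mode)
  validate_generator_config(unclass(config))
  pf_check(is.data.frame(roster) && nrow(roster) >= 1, "'roster' must be a non-empty roster")
  ndays <- as.integer(config$study_days)
  with_local_seed(seed, {
    grid <- expand.grid(hour = 0:23, day = seq_len(ndays), pen = seq_len(nrow(roster)),
                        KEEP.OUT.ATTRS = FALSE)
    out <- roster[grid$pen, , drop = FALSE]
    rownames(out) <- NULL
    out$day <- grid$day
    out$hour <- grid$hour
    truth <- out[, c("pen_id", "day", "hour")]
    for (resp in c("water", "activations")) {
      p <- config[[resp]]
      m <- if (mode == "harmonic") {
        harmonic_sqrt_mean(out$day, out$hour, p)
      } else {
        period_sqrt_mean(out$day, out$hour, config$period[[resp]], out$stock,
                         config$period$baseline_week)
      }
      pen_re <- rnorm(nrow(roster), 0, p$pen_sd)[grid$pen]
      day_re <- rnorm(nrow(roster) * ndays, 0, p$day_sd)[(grid$pen - 1L) * ndays + grid$day]
      eps <- ar1_noise(nrow(roster) * ndays, 24L, p$rho, p$resid_sd)
      s <- m + pen_re + day_re + eps
      out[[resp]] <- pmax(s, 0)^2
      truth[[paste0("sqrt_mean_", resp)]] <- m
      truth[[paste0("ranef_", resp)]] <- pen_re + day_re + eps
    }
    attr(out, "truth") <- truth
    attr(out, "mode") <- mode
    out
  })
}

#' Ground-truth components of a simulated table
#' @param x a table produced by [simulate_pen_hourly()].
#' @return the component `data.frame` stored alongside the simulated values.
#' @export
sim_truth <- function(x) {
  tr <- attr(x, "truth")
  pf_check(!is.null(tr), "no ground-truth attribute; was this table simulated?")
  tr
}

#' Split pen-level hours between the two drinking cups
#'
#' Partitions each pen-hour's water and activations between the feeder-side
#' (F) and opposite (OF) cup using a pen-specific preference share drawn from
#' a beta distribution with the configured mean/SD. On each day a pen
#' re-draws its share with probability `switch_prob` (emulating observed
#' preference switches). F + OF reproduces the pen value exactly.
#'
#' @inheritParams simulate_pen_hourly
#' @param pen_hourly pen-level hourly table.
#' @return sensor-level table: pen columns plus `location` ("F"/"OF"),
#'   `sensor_id`, and per-location `water`/`activations`.
#' @export
split_sensors <- function(pen_hourly, config = generator_config(), seed = NULL) {
  pf_check(all(c("pen_id", "day", "water", "activations") %in% names(pen_hourly)),
           "'pen_hourly' must be a pen-level hourly table")
  pr <- config$preference
  with_local_seed(seed, {
    pens <- unique(pen_hourly$pen_id)
    ndays <- max(pen_hourly$day)
    ## beta parameters by method of moments, guarded for tiny SDs
    draw_share <- function(n) {
      if (pr$f_share_sd <= 0 || pr$f_share_mean >= 1)
        return(rep(pr$f_share_mean, n))
      mu <- pr$f_share_mean
      v <- min(pr$f_share_sd^2, mu * (1 - mu) * 0.95)
      k <- mu * (1 - mu) / v - 1
      rbeta(n, mu * k, (1 - mu) * k)
    }
    ## share per pen-day with persistence until a switch
    share <- matrix(NA_real_, nrow = ndays, ncol = length(pens))
    share[1, ] <- draw_share(length(pens))
    if (ndays > 1) {
      for (d in 2:ndays) {
        sw <- runif(length(pens)) < pr$switch_prob
        share[d, ] <- ifelse(sw, draw_share(length(pens)), share[d - 1, ])
      }
    }
    idx <- cbind(pen_hourly$day, match(pen_hourly$pen_id, pens))
    s <- share[idx]
    f <- pen_hourly
    f$location <- "F"
    f$water <- pen_hourly$water * s
    f$activations <- pen_hourly$activations * s
    o <- pen_hourly
    o$location <- "OF"
    o$water <- pen_hourly$water - f$water
    o$activations <- pen_hourly$activations - f$activations
    out <- rbind(f, o)
    out$sensor_id <- paste0(out$pen_id, "-", out$location)
    attr(out, "truth") <- NULL
    ord <- order(match(out$pen_id, pens), out$location, out$day, out$hour)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Inject sensor-fault anomalies
#'
#' Corrupts randomly selected sensor-hours with one of three fault types:
#' a stuck nipple (constant high flow, a single activation), a slow leak
#' (small constant flow) or a dropout (all zero). Every corrupted cell is
#' recorded in a truth-label table.
#'
#' @param sensor_hourly sensor-level (or pen-level) hourly table.
#' @inheritParams simulate_pen_hourly
#' @return `list(data = corrupted table, labels = data.frame)` where labels
#'   hold the keys, fault `type` and the original values.
#' @export
inject_anomalies <- function(sensor_hourly, config = generator_config(), seed = NULL) {
  an <- config$anomaly
  pf_check(an$rate >= 0 && an$rate <= 1, "anomaly rate must lie in [0, 1]")
  keys <- intersect(c("pen_id", "location", "day", "hour"), names(sensor_hourly))
  with_local_seed(seed, {
    hit <- which(runif(nrow(sensor_hourly)) < an$rate)
    if (length(hit) == 0L) {
      labels <- cbind(sensor_hourly[0, keys, drop = FALSE],
                      type = character(0), water_orig = numeric(0),
                      activations_orig = numeric(0))
      return(list(data = sensor_hourly, labels = labels))
    }
    w <- an$weights / sum(an$weights)
    type <- sample(names(w), length(hit), replace = TRUE, prob = w)
    labels <- cbind(sensor_hourly[hit, keys, drop = FALSE],
                    type = type,
                    water_orig = sensor_hourly$water[hit],
                    activations_orig = sensor_hourly$activations[hit])
    rownames(labels) <- NULL
    n_pigs <- if ("n_pigs" %in% names(sensor_hourly)) sensor_hourly$n_pigs[hit] else 1
    out <- sensor_hourly
    out$water[hit] <- ifelse(type == "stuck", an$stuck_water,
                             ifelse(type == "leak", an$leak_water, 0))
    out$activations[hit] <- ifelse(type == "stuck", 1 / n_pigs,
                                   ifelse(type == "leak", 1 / n_pigs, 0))
    list(data = out, labels = labels)
  })
}

#' Schedule tail-damage events
#'
#' Draws at most one tail-damage event per pen from a constant per-pen-day
#' hazard over the study period. A pen leaves the study at its event, so
#' simulated data after the event day are discarded downstream.
#'
#' @inheritParams simulate_pen_hourly
#' @return `data.frame(pen_id, event_day)`, one row per event pen.
#' @export
schedule_tail_events <- function(roster, config = generator_config(), seed = NULL) {
  h <- config$events$hazard
  pf_check(h >= 0 && h <= 1, "event hazard must lie in [0, 1]")
  ndays <- as.integer(config$study_days)
  with_local_seed(seed, {
    if (h == 0) return(data.frame(pen_id = character(0), event_day = integer(0)))
    u <- runif(nrow(roster))
    ## day of first success of a geometric with probability h
    day <- ceiling(log1p(-u) / log1p(-h))
    keep <- day <= ndays
    data.frame(pen_id = roster$pen_id[keep], event_day = as.integer(day[keep]),
               stringsAsFactors = FALSE)
  })
}

#' Apply tail-damage case offsets and censor event pens
#'
#' Event pens receive an additive sqrt-scale shift per time period on every
#' simulated day (the study observed constant case-control differences,
#' independent of day relative to the event). The shift is solved from the
#' configured back-transformed offset at the period's mean level on the
#' baseline day. Hours after the event day are dropped (the pen exits the
#' study).
#'
#' @param pen_hourly pen-level hourly table.
#' @param events event log from [schedule_tail_events()].
#' @inheritParams simulate_pen_hourly
#' @return the modified pen-level table.
#' @export
apply_event_effects <- function(pen_hourly, events, config = generator_config()) {
  if (nrow(events) == 0L) return(pen_hourly)
  ev_day <- events$event_day[match(pen_hourly$pen_id, events$pen_id)]
  keep <- is.na(ev_day) | pen_hourly$day <= ev_day
  out <- pen_hourly[keep, , drop = FALSE]
  is_case <- !is.na(ev_day[keep])
  per <- as.character(assign_period(out$hour))
  for (resp in c("water", "activations")) {
    delta <- if (resp == "water") config$events$effect_water_bt else config$events$effect_act_bt
    m_base <- vapply(period_levels, function(pl) {
      hrs <- (0:23)[as.character(assign_period(0:23)) == pl]
      mean(harmonic_sqrt_mean(config$events$baseline_day, hrs, config[[resp]]))
    }, numeric(1))
    d <- sqrt_shift_onesided(delta[period_levels], m_base)
    names(d) <- period_levels
    shift <- ifelse(is_case, d[per], 0)
    out[[resp]] <- pmax(sqrt(out[[resp]]) + shift, 0)^2
  }
  rownames(out) <- NULL
  out
}

#' Emit a pulse-level flow-event stream
#'
#' Decomposes each sensor-hour into its activation count of drinking bouts
#' with start/stop timestamps inside the hour and pulse totals summing to
#' `round(liters * pulses_per_liter)`. Because pulses and activations are
#' integer-quantized, the function also returns the quantized hourly table
#' (`emitted`) that the stream reproduces exactly under [aggregate_hourly()].
#'
#' @param sensor_hourly sensor-level hourly table with `n_pigs`.
#' @param pulses_per_liter flow-meter resolution (> 0).
#' @param seed optional integer seed for bout placement.
#' @param start_date POSIXct study start (day 1, 00:00).
#' @return `list(events, emitted)`: `events` has sensor_id, pen_id, location,
#'   start, stop (POSIXct, second resolution) and pulses; `emitted` is the
#'   quantized hourly table.
#' @export
emit_pulse_stream <- function(sensor_hourly, pulses_per_liter = 1000, seed = NULL,
                              start_date = as.POSIXct("2015-06-01", tz = "UTC")) {
  pf_check(pulses_per_liter > 0, "'pulses_per_liter' must be > 0")
  pf_check(all(c("sensor_id", "n_pigs", "water", "activations") %in% names(sensor_hourly)),
           "'sensor_hourly' must carry sensor_id, n_pigs, water and activations")
  x <- sensor_hourly
  k <- as.integer(round(x$activations * x$n_pigs))
  pf_check(all(k <= 3600), "more than 3600 activations in one hour cannot fit distinct bouts")
  pulses <- as.integer(round(x$water * x$n_pigs * pulses_per_liter))
  pulses[k == 0L] <- 0L # no bout, no recordable flow
  emitted <- x
  emitted$water <- pulses / pulses_per_liter / x$n_pigs
  emitted$activations <- k / x$n_pigs
  rows <- which(k > 0L)
  with_local_seed(seed, {
    ev <- lapply(rows, function(i) {
      ki <- k[i]
      slot <- 3600 %/% ki
      width <- max(slot - 2L, 1L)
      start_s <- (seq_len(ki) - 1L) * slot +
        floor(runif(ki, 0, max(1, slot %/% 2)))
      stop_s <- pmin(start_s + pmax(1L, width %/% 2L), 3599L)
      p <- rep(pulses[i] %/% ki, ki)
      rem <- pulses[i] %% ki
      if (rem > 0L) p[seq_len(rem)] <- p[seq_len(rem)] + 1L
      base <- start_date + ((x$day[i] - 1) * 24 + x$hour[i]) * 3600
      data.frame(sensor_id = x$sensor_id[i], pen_id = x$pen_id[i],
                 location = x$location[i],
                 start = base + start_s, stop = base + stop_s,
                 pulses = as.integer(p), stringsAsFactors = FALSE)
    })
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(sensor_id = character(0), pen_id = character(0),
                 location = character(0),
                 start = as.POSIXct(character(0), tz = "UTC"),
                 stop = as.POSIXct(character(0), tz = "UTC"),
                 pulses = integer(0))
    list(events = events, emitted = emitted)
  })
}

#' Simulate a complete study
#'
#' Orchestrates the generator end to end: roster (optional), pen-level hourly
#' series, tail-damage events with case offsets and censoring, sensor split,
#' and anomaly injection. All randomness derives from `seed`.
#'
#' @inheritParams simulate_pen_hourly
#' @param roster optional roster; defaults to [roster_study_scale()].
#' @return a list: `roster`, `events`, `pen_hourly` (post-event-effect,
#'   pre-anomaly), `sensor_hourly` (anomaly-corrupted), `anomaly_labels`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config = generator_config(), roster = NULL, seed = NULL) {
  with_local_seed(seed, {
    if (is.null(roster)) roster <- roster_study_scale()
    base <- simulate_pen_hourly(roster, config)
    truth <- sim_truth(base)
    events <- schedule_tail_events(roster, config)
    pen_hourly <- apply_event_effects(base, events, config)
    sensor <- split_sensors(pen_hourly, config)
    anom <- inject_anomalies(sensor, config)
    list(roster = roster, events = events, pen_hourly = pen_hourly,
         sensor_hourly = anom$data, anomaly_labels = anom$labels,
         truth = truth, config = config)
  })
}
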
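#' Calibrate a flow sensor from repeated 1-litre trials
#'
#' Each trial extracts exactly one litre of water through the sensor and
#' records the pulse count; the calibration factor is the arithmetic mean of
#' the trial counts (pulses per litre).
#'
#' @param trial_counts numeric vector of pulse counts, one per 1-L trial.
#' @param sensor_id optional sensor identifier.
#' @return a list of class `sensor_calibration`: `sensor_id`,
#'   `pulses_per_liter`, `trial_counts`.
#' @examples
#' calibrate_sensor(c(980, 1000, 1020))$pulses_per_liter # 1000
#' @export
calibrate_sensor <- function(trial_counts, sensor_id = NULL) {
  pf_check(length(trial_counts) >= 1 && is.numeric(trial_counts),
           "at least one numeric trial count is required")
  pf_check(all(trial_counts > 0), "trial counts must be positive")
  if (length(trial_counts) < 3)
    warning("calibration from ", length(trial_counts),
            " trial(s); three trials per sensor are the standard protocol")
  structure(list(sensor_id = sensor_id,
                 pulses_per_liter = mean(trial_counts),
                 trial_counts = trial_counts),
            class = "sensor_calibration")
}

#' Percent drift between two calibrations of one sensor
#'
#' Re-calibrating a sensor after a period of use quantifies its inaccuracy as
#' `100 * |new - old| / old` percent.
#'
#' @param old,new `sensor_calibration` objects for the same sensor.
#' @return percent inaccuracy (non-negative scalar).
#' @examples
#' recalibration_drift(calibrate_sensor(rep(1000, 3)),
#'                     calibrate_sensor(rep(1080, 3))) # 8
#' @export
recalibration_drift <- function(old, new) {
  pf_check(inherits(old, "sensor_calibration") && inherits(new, "sensor_calibration"),
           "'old' and 'new' must be sensor_calibration objects")
  if (!is.null(old$sensor_id) && !is.null(new$sensor_id) &&
      !identical(old$sensor_id, new$sensor_id))
    pf_stop("calibrations are for different sensors: ",
            old$sensor_id, " vs ", new$sensor_id)
  100 * abs(new$pulses_per_liter - old$pulses_per_liter) / old$pulses_per_liter
}

#' Aggregate pulse-level flow events to hourly sensor use
#'
#' Converts start/stop flow events into per-sensor hourly water use (litres
#' per pig) and activation frequency (starts per pig). An event is counted,
#' with all its pulses, in the hour of its start record. Hours with no events
#' are materialized as explicit zero rows over the full study grid (required
#' for the AR(1) hour lattice downstream).
#'
#' @param events data.frame with `sensor_id`, `pen_id`, `location`, `start`
#'   (POSIXct), `stop`, `pulses`.
#' @param calibration a single `sensor_calibration`, a list of them keyed by
#'   sensor id, or a data.frame with `sensor_id` and `pulses_per_liter`.
#' @param pen_meta pen roster (for `n_pigs` and batch/treatments).
#' @param study_days number of days in the output grid (default: last day
#'   seen in the events).
#' @param start_date POSIXct study start; day 1 begins here.
#' @return sensor-level hourly table (one row per sensor x day x hour).
#' @export
aggregate_hourly <- function(events, calibration, pen_meta,
                             study_days = NULL,
                             start_date = as.POSIXct("2015-06-01", tz = "UTC")) {
  pf_check(all(c("sensor_id", "pen_id", "location", "start", "pulses") %in% names(events)),
           "'events' must have sensor_id, pen_id, location, start, pulses")
  pf_check(all(events$pulses >= 0), "negative pulse counts are invalid")
  ppl <- calibration_lookup(calibration)
  sensors_seen <- unique(events$sensor_id)
  if (!is.null(names(ppl))) {
    unknown <- setdiff(sensors_seen, names(ppl))
    if (length(unknown))
      pf_stop("events from sensors without calibration: ",
              paste(unknown, collapse = ", "))
  }
  unknown_pen <- setdiff(unique(events$pen_id), pen_meta$pen_id)
  if (length(unknown_pen))
    pf_stop("events from pens not in 'pen_meta': ", paste(unknown_pen, collapse = ", "))

  secs <- as.numeric(difftime(events$start, start_date, units = "secs"))
  pf_check(all(secs >= 0), "events before 'start_date'")
  day <- as.integer(secs %/% 86400) + 1L
  hour <- as.integer((secs %% 86400) %/% 3600)
  if (is.null(study_days)) study_days <- max(day)

  ## full grid: both locations for every pen, every day/hour
  grid <- expand.grid(hour = 0:23, day = seq_len(study_days),
                      location = c("F", "OF"),
                      pen_id = pen_meta$pen_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(p, l, d, h) paste(p, l, d, h, sep = "\r")
  ev_ppl <- if (is.null(names(ppl))) rep(ppl, nrow(events)) else ppl[events$sensor_id]
  liters <- events$pulses / ev_ppl
  kk <- key(events$pen_id, events$location, day, hour)
  wat <- rowsum(liters, kk)
  act <- rowsum(rep(1, nrow(events)), kk)
  gk <- key(grid$pen_id, grid$location, grid$day, grid$hour)
  i <- match(gk, rownames(wat))
  meta_i <- match(grid$pen_id, pen_meta$pen_id)
  out <- cbind(pen_meta[meta_i, , drop = FALSE], grid[c("location", "day", "hour")])
  out$sensor_id <- paste0(out$pen_id, "-", out$location)
  out$water <- ifelse(is.na(i), 0, wat[i]) / out$n_pigs
  out$activations <- ifelse(is.na(i), 0, act[i]) / out$n_pigs
  ord <- order(meta_i, out$location, out$day, out$hour)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

calibration_lookup <- function(calibration) {
  if (inherits(calibration, "sensor_calibration")) return(calibration$pulses_per_liter)
  if (is.data.frame(calibration)) {
    pf_check(all(c("sensor_id", "pulses_per_liter") %in% names(calibration)),
             "calibration data.frame needs sensor_id and pulses_per_liter")
    return(setNames(calibration$pulses_per_liter, calibration$sensor_id))
  }
  if (is.list(calibration)) {
    ppl <- vapply(calibration, function(c) c$pulses_per_liter, numeric(1))
    ids <- vapply(calibration, function(c) as.character(c$sensor_id), character(1))
    return(setNames(ppl, ids))
  }
  if (is.numeric(calibration) && length(calibration) == 1) return(calibration)
  pf_stop("unsupported 'calibration' object")
}

#' Aggregate sensor-level hours to pen level
#'
#' Pen-level use is the sum of the two cup sensors (F + OF) per hour. Pens
#' listed in `exclusions` (e.g. broken sensors) are dropped; pens missing one
#' of the two locations are flagged and excluded with a message.
#'
#' @param sensor_hourly sensor-level hourly table.
#' @param exclusions character vector of pen ids to drop, or a data.frame
#'   with `pen_id` and `reason`.
#' @return pen-level hourly table (per-pig normalization preserved).
#' @export
pen_level <- function(sensor_hourly, exclusions = NULL) {
  excl <- if (is.data.frame(exclusions)) exclusions$pen_id else exclusions
  x <- sensor_hourly[!(sensor_hourly$pen_id %in% excl), , drop = FALSE]
  locs <- tapply(x$location, x$pen_id, function(l) length(unique(l)))
  bad <- names(locs)[locs < 2]
  if (length(bad)) {
    message("excluding pen(s) with a missing sensor location: ",
            paste(bad, collapse = ", "))
    x <- x[!(x$pen_id %in% bad), , drop = FALSE]
  }
  f <- x[x$location == "F", , drop = FALSE]
  o <- x[x$location == "OF", , drop = FALSE]
  ko <- paste(o$pen_id, o$day, o$hour, sep = "\r")
  i <- match(paste(f$pen_id, f$day, f$hour, sep = "\r"), ko)
  pf_check(!anyNA(i) && nrow(f) == nrow(o),
           "sensor locations are not aligned on the same pen-day-hour grid")
  out <- f
  out$water <- f$water + o$water[i]
  out$activations <- f$activations + o$activations[i]
  out$location <- NULL
  out$sensor_id <- NULL
  rownames(out) <- NULL
  out
}
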
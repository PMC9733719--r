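#' Pipeline configuration
#'
#' Collects every knob of [run_pipeline()]: the generator configuration (for
#' simulation mode), cleaning threshold, model options and analysis toggles.
#' Can be loaded from a JSON file with [load_pipeline_config()]; unknown
#' fields are rejected.
#'
#' @param seed integer seed recorded in every output header.
#' @param generator a [generator_config()] (or a plain list of overrides).
#' @param roster_scale `"study"` (112 pens, 4 batches) or a number of pens
#'   per treatment combination for a single-batch roster.
#' @param cleaning_k residual-SD threshold (set `NA` to skip cleaning).
#' @param select run backward elimination in the period/event models (slow).
#' @param analyses character subset of
#'   `c("diurnal", "periods", "location", "events")`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, generator = generator_config(),
                            roster_scale = "study", cleaning_k = 4,
                            select = FALSE,
                            analyses = c("diurnal", "periods", "location", "events")) {
  if (!inherits(generator, "generator_config"))
    generator <- do.call(generator_config, as.list(generator))
  structure(list(seed = as.integer(seed), generator = generator,
                 roster_scale = roster_scale, cleaning_k = cleaning_k,
                 select = select, analyses = analyses),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with any subset of the `pipeline_config` fields.
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "generator", "roster_scale", "cleaning_k", "select", "analyses")
  extra <- setdiff(names(raw), known)
  pf_check(length(extra) == 0, "unknown config fields: ", paste(extra, collapse = ", "))
  do.call(pipeline_config, raw)
}

## delimited text with a one-line schema/seed header
write_stage_table <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pigflow v%s; seed=%d; written=%s",
                     as.character(utils::packageVersion("pigflow")), seed,
                     "deterministic"), con)
  write.csv(df, con, row.names = FALSE)
}

#' Read a pipeline stage table
#' @param path a CSV written by [run_pipeline()] (one `#` header line).
#' @return data.frame.
#' @export
read_stage_table <- function(path) read.csv(path, comment.char = "#")

#' Run the full analysis pipeline
#'
#' Simulation mode end to end: simulate a study, aggregate to pen level,
#' clean, fit the harmonic diurnal/age-trend models on never-damaged pens,
#' run the period-by-week-by-treatment analysis, the paired cup-location
#' comparison and the matched-pair event analysis. All intermediate tables
#' are written as headered CSV under `out_dir` together with a Markdown
#' report; every stage logs its row counts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return (invisibly) a list with every intermediate table and fit.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  pf_check(inherits(config, "pipeline_config"), "'config' must be a pipeline_config")
  seed <- config$seed
  stage <- function(...) message("[pigflow] ", ...)
  roster <- if (identical(config$roster_scale, "study")) roster_study_scale(seed) else
    generate_pen_roster(as.integer(config$roster_scale), 1, seed)
  stage("roster: ", nrow(roster), " pens")
  sim <- simulate_study(config$generator, roster, seed = seed + 1L)
  stage("simulated ", nrow(sim$sensor_hourly), " sensor-hours; ",
        nrow(sim$events), " tail-damage events; ",
        nrow(sim$anomaly_labels), " injected anomalies")
  pen_hourly <- pen_level(sim$sensor_hourly)
  stage("pen level: ", nrow(pen_hourly), " pen-hours")

  if (is.na(config$cleaning_k)) {
    cleaned <- pen_hourly
    report <- NULL
    stage("cleaning skipped")
  } else {
    cl <- clean_dataset(pen_hourly, k = config$cleaning_k)
    cleaned <- cl$data
    report <- cl$report
    stage("cleaning: ",
          paste(sprintf("%s %d/%d flagged", report$summary$response,
                        report$summary$n_flagged, report$summary$n_input),
                collapse = "; "))
  }
  never <- setdiff(roster$pen_id, sim$events$pen_id)
  normal <- cleaned[cleaned$pen_id %in% never, , drop = FALSE]
  stage("never-damaged pens: ", length(never))

  res <- list(roster = roster, events = sim$events, pen_hourly = pen_hourly,
              cleaned = cleaned, cleaning_report = report, config = config)

  if ("diurnal" %in% config$analyses) {
    res$harmonic_water <- fit_harmonic_mixed(normal, "water")
    res$harmonic_act <- fit_harmonic_mixed(normal, "activations")
    stage("harmonic fits done (converged: ",
          res$harmonic_water$converged && res$harmonic_act$converged, ")")
  }
  if ("periods" %in% config$analyses) {
    res$period_water <- fit_period_model(normal, "water", select = config$select)
    res$period_act <- fit_period_model(normal, "activations", select = config$select)
    res$period_contrasts_water <- period_contrasts(res$period_water)
    res$period_contrasts_act <- period_contrasts(res$period_act)
    res$low_share <- low_period_share_test(normal, "stock", "water")
    stage("period models done")
  }
  if ("location" %in% config$analyses) {
    sens <- if (is.null(report)) sim$sensor_hourly else
      apply_cleaning(sim$sensor_hourly, report)
    res$location_summaries <- location_means(sens[sens$pen_id %in% never, , drop = FALSE])
    res$location_water <- location_table(res$location_summaries, "water")
    res$location_act <- location_table(res$location_summaries, "activations")
    stage("location analysis done")
  }
  if ("events" %in% config$analyses && nrow(sim$events) > 0) {
    mp <- match_pairs(sim$events, roster)
    res$pairs <- mp$pairs
    res$pairs_dropped <- mp$dropped
    if (nrow(mp$pairs) >= 2) {
      res$window <- window_summaries(cleaned, mp$pairs)
      res$event_water <- fit_event_model(res$window, "mean", "water",
                                         select = config$select)
      res$event_contrasts_water <- event_contrasts(res$event_water)
      res$event_low_share <- low_share_event_tests(res$window)
    }
    stage("event analysis done: ", nrow(mp$pairs), " pairs")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) if (!is.null(df))
      write_stage_table(df, file.path(out_dir, paste0(name, ".csv")), seed)
    w(roster, "roster")
    w(sim$events, "events")
    w(pen_hourly, "pen_hourly")
    w(cleaned, "pen_hourly_cleaned")
    if (!is.null(report)) w(report$summary, "cleaning_summary")
    if (!is.null(res$location_water)) w(res$location_water, "location_water")
    if (!is.null(res$pairs)) w(res$pairs, "pairs")
    writeLines(render_report(res), file.path(out_dir, "report.md"))
    stage("outputs written to ", out_dir)
  }
  invisible(res)
}

## Markdown report mirroring the standard result layout
render_report <- function(res) {
  fmt <- function(df) c(paste(names(df), collapse = " | "),
                        paste(rep("---", ncol(df)), collapse = " | "),
                        apply(df, 1, function(r) paste(format(r, digits = 4),
                                                       collapse = " | ")))
  out <- c("# pigflow run report", "",
           paste0("seed: ", res$config$seed), "")
  if (!is.null(res$cleaning_report)) {
    out <- c(out, "## Cleaning", "", fmt(res$cleaning_report$summary), "")
  }
  if (!is.null(res$harmonic_water)) {
    hw <- res$harmonic_water
    out <- c(out, "## Diurnal / age-trend parameters (sqrt scale)", "",
             sprintf("- water: initial mean %.4f, daily trend %.6f", hw$mu0, hw$trend),
             sprintf("- activations: initial mean %.4f, daily trend %.6f",
                     res$harmonic_act$mu0, res$harmonic_act$trend), "",
             fmt(hw$waves[, c("wave", "A", "b", "c")]), "",
             sprintf("- model-estimated water use, day %d: %.2f L/pig/day",
                     round(mean(hw$day_range)),
                     daily_total(hw, round(mean(hw$day_range)))), "")
  }
  if (!is.null(res$period_contrasts_water)) {
    out <- c(out, "## Period x stocking contrasts (back-transformed)", "",
             fmt(res$period_contrasts_water$diffs), "")
  }
  if (!is.null(res$location_water)) {
    out <- c(out, "## Cup-location comparison (water)", "", fmt(res$location_water), "")
  }
  if (!is.null(res$event_contrasts_water)) {
    out <- c(out, "## Tail-damage case-control contrasts (water, mean statistic)", "",
             fmt(res$event_contrasts_water), "")
  }
  out
}
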
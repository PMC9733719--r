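#' Fit the per-batch cleaning model
#'
#' A fixed-effects Gaussian linear model of one batch's pen-level hourly
#' response accounting for the age trend and the diurnal pattern: OLS of the
#' (by default square-root transformed) response on day, three sine/cosine
#' harmonic pairs, and day-by-harmonic interactions. Deliberately simpler
#' than the inferential mixed models: it only supplies fitted values and a
#' batch-wide residual SD for outlier flagging.
#'
#' @param batch_data pen-level hourly rows of a single batch.
#' @param response `"water"` or `"activations"`.
#' @param sqrt_scale model on the square-root scale (default) or raw scale.
#' @return list: `fitted` (model scale, one per row), `resid_sd`,
#'   `coefficients`, `response`, `sqrt_scale`.
#' @export
fit_cleaning_model <- function(batch_data, response = c("water", "activations"),
                               sqrt_scale = TRUE) {
  response <- match.arg(response)
  X <- build_harmonic_design(batch_data)
  pf_check(nrow(X) > ncol(X), "fewer rows than model parameters in this batch")
  y <- batch_data[[response]]
  ok <- !is.na(y)
  y <- if (sqrt_scale) sqrt(y) else y
  fit <- lm.fit(X[ok, , drop = FALSE], y[ok])
  fitted <- rep(NA_real_, nrow(X))
  fitted[ok] <- fit$fitted.values
  resid_sd <- sqrt(sum(fit$residuals^2) / (sum(ok) - fit$rank))
  list(fitted = fitted, resid_sd = resid_sd, coefficients = fit$coefficients,
       response = response, sqrt_scale = sqrt_scale)
}

## The flagging rule: strictly more than k residual SDs from the fitted value.
flag_outliers <- function(obs, fitted, resid_sd, k) {
  abs(obs - fitted) > k * resid_sd
}

#' Remove sensor-error outliers with a residual-SD rule
#'
#' For each batch and each response independently, fits the cleaning model
#' ([fit_cleaning_model()]) and flags observation hours deviating strictly
#' more than `k` residual standard deviations from their fitted values
#' (single pass: fit once, flag once). Flagged cells are set to `NA` in the
#' returned table, so the water and activation masks may differ.
#'
#' @param pen_hourly pen-level hourly table with a `batch` column.
#' @param k flagging threshold in residual SDs (> 0; default 4).
#' @param responses responses to clean.
#' @param sqrt_scale passed to [fit_cleaning_model()].
#' @return list: `data` (table with flagged cells `NA`), `report` (class
#'   `cleaning_report`: per-response counts and fractions, per-batch residual
#'   SDs, and the flag mask keyed by pen, day, hour, response).
#' @export
clean_dataset <- function(pen_hourly, k = 4,
                          responses = c("water", "activations"),
                          sqrt_scale = TRUE) {
  pf_check(is.numeric(k) && length(k) == 1 && k > 0, "'k' must be a positive number")
  pf_check("batch" %in% names(pen_hourly), "'pen_hourly' must carry a 'batch' column")
  out <- pen_hourly
  flags <- list()
  batch_sd <- list()
  summary_rows <- list()
  for (resp in responses) {
    flagged <- logical(nrow(out))
    for (b in unique(pen_hourly$batch)) {
      rows <- which(pen_hourly$batch == b)
      fit <- fit_cleaning_model(pen_hourly[rows, , drop = FALSE], resp, sqrt_scale)
      obs <- pen_hourly[[resp]][rows]
      obs_m <- if (sqrt_scale) sqrt(obs) else obs
      fl <- flag_outliers(obs_m, fit$fitted, fit$resid_sd, k)
      fl[is.na(fl)] <- FALSE
      flagged[rows[fl]] <- TRUE
      batch_sd[[length(batch_sd) + 1L]] <-
        data.frame(response = resp, batch = b, resid_sd = fit$resid_sd)
    }
    n_in <- sum(!is.na(pen_hourly[[resp]]))
    out[[resp]][flagged] <- NA_real_
    flags[[resp]] <- data.frame(pen_id = pen_hourly$pen_id[flagged],
                                day = pen_hourly$day[flagged],
                                hour = pen_hourly$hour[flagged],
                                response = rep(resp, sum(flagged)),
                                stringsAsFactors = FALSE)
    summary_rows[[resp]] <- data.frame(
      response = resp, n_input = n_in, n_flagged = sum(flagged),
      n_retained = n_in - sum(flagged),
      fraction_flagged = sum(flagged) / n_in)
  }
  report <- structure(list(summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
                           batch_sd = do.call(rbind, c(batch_sd, make.row.names = FALSE)),
                           flags = do.call(rbind, c(flags, make.row.names = FALSE)),
                           k = k, sqrt_scale = sqrt_scale),
                      class = "cleaning_report")
  list(data = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Outlier cleaning (", x$k, " residual-SD rule, ",
      if (x$sqrt_scale) "sqrt" else "raw", " scale)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Propagate a cleaning mask to another table
#'
#' Sets to `NA` the cells of `table` (e.g. the sensor-level data) whose
#' (pen, day, hour, response) were flagged in a [clean_dataset()] report, so
#' sensor-level analyses exclude exactly the hours ignored at pen level.
#'
#' @param table an hourly table with `pen_id`, `day`, `hour`.
#' @param report a `cleaning_report`.
#' @return the masked table.
#' @export
apply_cleaning <- function(table, report) {
  pf_check(inherits(report, "cleaning_report"), "'report' must be a cleaning_report")
  key <- paste(table$pen_id, table$day, table$hour, sep = "\r")
  for (resp in unique(report$flags$response)) {
    fl <- report$flags[report$flags$response == resp, , drop = FALSE]
    hit <- key %in% paste(fl$pen_id, fl$day, fl$hour, sep = "\r")
    table[[resp]][hit] <- NA_real_
  }
  table
}
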
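#' Match tail-damage pens to control pens
#'
#' Pairs each tail-damage pen with an eligible control: a pen from the same
#' batch with the same levels of all three treatments drawn from the
#' "no tail damage" pool — by default a pen with no event at all
#' (`clear_after = Inf`); setting `clear_after = 7` relaxes this to the
#' minimal clause that the control has no event on or before
#' `day0 + clear_after`. Among eligible controls the
#' one in closest room proximity (smallest absolute position difference,
#' ties to the lower position) is chosen. Controls may be reused across
#' events; reuse is flagged. Events whose day-0 window would start before
#' the study (day0 <= `window_days`) are dropped with a logged reason, as are
#' events with no eligible control.
#'
#' @param events event log (`pen_id`, `event_day`).
#' @param roster pen roster.
#' @param event_history event log used to judge control eligibility
#'   (defaults to `events`).
#' @param window_days days before day-0 required for analysis (default 3).
#' @param clear_after days after day-0 a control must stay event-free
#'   (default `Inf`: controls are never-damaged pens).
#' @return list: `pairs` (event_id, case, control, day0, batch, treatments,
#'   control_reused) and `dropped` (pen_id, day0, reason).
#' @export
match_pairs <- function(events, roster, event_history = events,
                        window_days = 3, clear_after = Inf) {
  pf_check(all(events$pen_id %in% roster$pen_id), "events reference unknown pens")
  hist_day <- setNames(event_history$event_day, event_history$pen_id)
  pairs <- list(); dropped <- list(); used <- character(0)
  ord <- order(events$event_day, events$pen_id)
  for (i in ord) {
    case <- events$pen_id[i]; day0 <- events$event_day[i]
    if (day0 <= window_days) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        pen_id = case, day0 = day0,
        reason = sprintf("event on day %d: day -%d..0 window incomplete", day0, window_days))
      next
    }
    cm <- roster[roster$pen_id == case, ]
    cand <- roster[roster$pen_id != case &
                     roster$batch == cm$batch &
                     roster$tail == cm$tail &
                     roster$straw == cm$straw &
                     roster$stock == cm$stock, , drop = FALSE]
    cd <- hist_day[cand$pen_id]
    cand <- cand[is.na(cd) | cd > day0 + clear_after, , drop = FALSE]
    if (!nrow(cand)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        pen_id = case, day0 = day0, reason = "no eligible control pen")
      next
    }
    dist <- abs(cand$position - cm$position)
    cand <- cand[order(dist, cand$position), , drop = FALSE]
    ctrl <- cand$pen_id[1]
    pairs[[length(pairs) + 1L]] <- data.frame(
      event_id = NA_integer_, case = case, control = ctrl, day0 = day0,
      batch = cm$batch, tail = cm$tail, straw = cm$straw, stock = cm$stock,
      control_reused = ctrl %in% used, stringsAsFactors = FALSE)
    used <- c(used, ctrl)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(event_id = integer(0), case = character(0), control = character(0),
               day0 = integer(0))
  if (nrow(pairs)) pairs$event_id <- seq_len(nrow(pairs))
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(pen_id = character(0), day0 = integer(0), reason = character(0))
  if (nrow(dropped))
    message(nrow(dropped), " event(s) dropped during matching (see $dropped)")
  list(pairs = pairs, dropped = dropped)
}

#' Period summaries over the day -3..0 window
#'
#' For each matched pair, each pen (case and control observed on the case's
#' calendar days), each day offset -3..0 and each time period: the total,
#' minimum, mean and maximum of the observed hourly values for both
#' responses. Statistics use observed (non-missing) hours; a period with no
#' observed hours is flagged (`n_hours = 0`, statistics `NA`) and marks the
#' pair incomplete.
#'
#' @param pen_hourly (cleaned) pen-level hourly table.
#' @param pairs the `pairs` element from [match_pairs()].
#' @param window_days days before day-0 to summarize (default 3).
#' @return long data.frame: event_id, pen_id, pen_type, stock, day0,
#'   day_offset, period, n_hours and `<resp>_{total,min,mean,max}` columns.
#' @export
window_summaries <- function(pen_hourly, pairs, window_days = 3) {
  pf_check(nrow(pairs) >= 1, "no pairs to summarize")
  key <- paste(pen_hourly$pen_id, pen_hourly$day, sep = "\r")
  per <- assign_period(pen_hourly$hour)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (type in c("case", "control")) {
      pen <- pairs[[if (type == "case") "case" else "control"]][i]
      for (off in seq(-window_days, 0)) {
        day <- pairs$day0[i] + off
        sel <- which(key == paste(pen, day, sep = "\r"))
        for (pl in period_levels) {
          ss <- sel[as.character(per[sel]) == pl]
          row <- data.frame(event_id = pairs$event_id[i], pen_id = pen,
                            pen_type = type, stock = as.character(pairs$stock[i]),
                            day0 = pairs$day0[i], day_offset = off, period = pl,
                            stringsAsFactors = FALSE)
          for (resp in c("water", "activations")) {
            v <- pen_hourly[[resp]][ss]
            v <- v[!is.na(v)]
            pre <- if (resp == "water") "water" else "act"
            if (length(v)) {
              row[[paste0(pre, "_total")]] <- sum(v)
              row[[paste0(pre, "_min")]] <- min(v)
              row[[paste0(pre, "_mean")]] <- mean(v)
              row[[paste0(pre, "_max")]] <- max(v)
            } else {
              row[paste0(pre, c("_total", "_min", "_mean", "_max"))] <- NA_real_
            }
          }
          row$n_hours <- length(ss[!is.na(pen_hourly$water[ss])])
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  incomplete <- unique(out$event_id[out$n_hours == 0])
  if (length(incomplete))
    message("pair(s) with incomplete windows: ", paste(incomplete, collapse = ", "))
  attr(out, "incomplete") <- incomplete
  out
}

#' Fit the matched-pair event model
#'
#' Linear mixed model of one window statistic (total on the original scale;
#' min/mean/max square-root transformed): fixed effects pen type, time
#' period, day offset (categorical, day -3 reference), age at day-0
#' (continuous, in study days) and stocking density, plus all pairwise
#' interactions among pen type, day, period and stocking; random intercepts
#' for day within pen within event, AR(1) across the period sequence within
#' a pen-day. Backward elimination as in [fit_period_model()] when
#' `select = TRUE`.
#'
#' @param summaries output of [window_summaries()] (incomplete pairs are
#'   dropped).
#' @param statistic one of `"mean"`, `"min"`, `"max"`, `"total"`.
#' @param response `"water"` or `"activations"`.
#' @param alpha elimination significance level.
#' @param select run backward elimination.
#' @param keep_model keep the `lme` object.
#' @return object of class `event_fit` (see [event_contrasts()]).
#' @export
fit_event_model <- function(summaries, statistic = c("mean", "min", "max", "total"),
                            response = c("water", "activations"),
                            alpha = 0.05, select = TRUE, keep_model = FALSE) {
  statistic <- match.arg(statistic)
  response <- match.arg(response)
  pre <- if (response == "water") "water" else "act"
  col <- paste0(pre, "_", statistic)
  d <- summaries
  bad <- attr(summaries, "incomplete")
  if (length(bad)) d <- d[!(d$event_id %in% bad), , drop = FALSE]
  d <- d[!is.na(d[[col]]), , drop = FALSE]
  n_pairs <- length(unique(d$event_id))
  if (n_pairs < 10)
    warning("only ", n_pairs, " complete pairs; the model may be unstable ",
            "(documented floor is 10)")
  sqrt_scale <- statistic != "total"
  d$y <- if (sqrt_scale) sqrt(d[[col]]) else d[[col]]
  d$pen_type <- factor(d$pen_type, levels = c("control", "case"))
  d$period <- factor(d$period, levels = period_levels)
  d$dayf <- factor(d$day_offset)
  d$stock <- factor(d$stock)
  d$age0 <- d$day0
  d$eventf <- factor(d$event_id)
  d$pen <- factor(paste(d$event_id, d$pen_id)) # a reused control is its own series per event
  d$pidx <- as.integer(d$period)
  single_stock <- nlevels(droplevels(d$stock)) < 2
  full_terms <- c("pen_type", "period", "dayf", "age0",
                  "pen_type:period", "pen_type:dayf", "period:dayf")
  if (var(d$age0) == 0) { # all events on one day: age is not estimable
    full_terms <- setdiff(full_terms, "age0")
    d$age0 <- 0
  }
  if (!single_stock)
    full_terms <- c(full_terms, "stock", "pen_type:stock", "period:stock", "dayf:stock")
  X <- model.matrix(as.formula(paste("~", paste(full_terms, collapse = " + "))), d)
  if (qr(X)$rank < ncol(X))
    pf_stop("rank-deficient event design (an interaction cell is empty); ",
            "offending columns: ",
            paste(colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]], collapse = ", "))
  random <- ~ 1 | eventf/pen/dayf
  ar_form <- ~ pidx | eventf/pen/dayf
  if (select) {
    sel <- backward_eliminate("y", full_terms, d, random, ar_form, alpha)
    retained <- sel$retained; elim_log <- sel$log
  } else {
    retained <- full_terms; elim_log <- NULL
  }
  if (!length(retained)) retained <- "1"
  fml <- as.formula(paste("y ~", paste(retained, collapse = " + ")))
  fit <- tryCatch(
    lme_robust(fml, data = d, random = random, ar_form = ar_form,
               method = "REML"),
    error = function(e) pf_stop("event model did not converge: ", conditionMessage(e)))
  vc <- suppressWarnings(as.numeric(nlme::VarCorr(fit)[, "StdDev"]))
  vc <- vc[!is.na(vc)]
  names(vc) <- c("event", "pen", "day", "residual")
  structure(list(
    response = response, statistic = statistic, sqrt_scale = sqrt_scale,
    n_pairs = n_pairs, retained = retained, elim_log = elim_log,
    fixef = nlme::fixef(fit), vcov = as.matrix(fit$varFix),
    se = sqrt(diag(as.matrix(fit$varFix))),
    varcomp = vc, rho = unname(coef(fit$modelStruct$corStruct, unconstrained = FALSE)),
    formula = paste(deparse(fml), collapse = ""),
    xlev = lapply(d[c("pen_type", "period", "dayf", "stock")], levels),
    margins = list(dayf = prop.table(table(d$dayf)),
                   stock = prop.table(table(unique(d[c("event_id", "stock")])$stock)),
                   age0 = mean(d$day0)),
    alpha = alpha, logLik = as.numeric(logLik(fit)),
    model = if (keep_model) fit else NULL
  ), class = "event_fit")
}

#' @export
print.event_fit <- function(x, ...) {
  cat("Matched-pair event model of ", if (x$sqrt_scale) "sqrt(" else "",
      x$response, "_", x$statistic, if (x$sqrt_scale) ")" else "",
      " on ", x$n_pairs, " pairs\n", sep = "")
  cat("  retained terms:", paste(x$retained, collapse = ", "), "\n")
  print(event_contrasts(x), row.names = FALSE, digits = 4)
  invisible(x)
}

## aggregated design row for a pen_type x period cell, marginal over day
## offset and stocking, age at its mean
event_design_row <- function(fit, pen_type, period) {
  rhs <- as.formula(paste("~", sub("^.*~", "", fit$formula)))
  Xagg <- 0
  for (dl in fit$xlev$dayf) for (kl in fit$xlev$stock) {
    w <- fit$margins$dayf[[dl]] * fit$margins$stock[[kl]]
    df <- data.frame(pen_type = factor(pen_type, levels = fit$xlev$pen_type),
                     period = factor(period, levels = fit$xlev$period),
                     dayf = factor(dl, levels = fit$xlev$dayf),
                     stock = factor(kl, levels = fit$xlev$stock),
                     age0 = fit$margins$age0)
    Xagg <- Xagg + w * model.matrix(rhs, df)
  }
  Xagg
}

#' Back-transformed case-control contrasts per time period
#'
#' Marginal model estimates (day offset and stocking averaged over their
#' observed distributions, age at its mean) per pen type and period,
#' back-transformed by squaring for sqrt-scale statistics, and the
#' case-minus-control difference with delta-method SEs.
#'
#' @param fit an `event_fit`.
#' @return data.frame: period, estimate per pen type (back-transformed),
#'   `diff` (case - control) and `se_diff`.
#' @export
event_contrasts <- function(fit) {
  pf_check(inherits(fit, "event_fit"), "'fit' must be an event_fit")
  rows <- lapply(fit$xlev$period, function(p) {
    Xc <- event_design_row(fit, "case", p)
    X0 <- event_design_row(fit, "control", p)
    mc <- drop(Xc %*% fit$fixef); m0 <- drop(X0 %*% fit$fixef)
    if (fit$sqrt_scale) {
      g <- 2 * mc * Xc - 2 * m0 * X0
      est_c <- mc^2; est_0 <- m0^2
    } else {
      g <- Xc - X0
      est_c <- mc; est_0 <- m0
    }
    se <- sqrt(drop(g %*% fit$vcov %*% t(g)))
    data.frame(period = p, case = est_c, control = est_0,
               diff = est_c - est_0, se_diff = se)
  })
  do.call(rbind, rows)
}

#' Low-period share tests around tail-damage events
#'
#' The share of use falling in the Low period, one observation per pen-day
#' from the window totals: compared between pen types with a Mann-Whitney U
#' test (23 pairs x 4 days = 92 observations per type at the study scale) and
#' across day offsets with a Kruskal-Wallis test (46 pens per day group).
#'
#' @param summaries output of [window_summaries()].
#' @param response `"water"` or `"activations"`.
#' @return list with elements `pen_type` (Mann-Whitney) and `day`
#'   (Kruskal-Wallis), each holding statistic, p.value, method and the
#'   pen-day `shares` used.
#' @export
low_share_event_tests <- function(summaries, response = c("water", "activations")) {
  response <- match.arg(response)
  pre <- if (response == "water") "water" else "act"
  col <- paste0(pre, "_total")
  d <- summaries[!is.na(summaries[[col]]), , drop = FALSE]
  pd_key <- paste(d$event_id, d$pen_id, d$day_offset)
  tot <- rowsum(d[[col]], pd_key)
  low <- rowsum(d[[col]] * (d$period == "Low"), pd_key)
  i <- match(rownames(tot), pd_key)
  shares <- data.frame(key = rownames(tot),
                       pen_type = d$pen_type[i], day_offset = d$day_offset[i],
                       share_low = low[, 1] / tot[, 1], row.names = NULL)
  x <- shares$share_low[shares$pen_type == "case"]
  y <- shares$share_low[shares$pen_type == "control"]
  pf_check(length(x) >= 2 && length(y) >= 2, "degenerate pen-type groups")
  mw <- mw_test(x, y)
  kw <- kruskal.test(shares$share_low, factor(shares$day_offset))
  list(pen_type = list(statistic = unname(mw$statistic), p.value = mw$p.value,
                       method = mw$method, shares = shares),
       day = list(statistic = unname(kw$statistic), p.value = kw$p.value,
                  method = kw$method, shares = shares))
}
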
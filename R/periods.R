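#' Assign an hour of day to its time period
#'
#' The day is segmented by the diurnal pattern into "Peak1" (06:00-11:59),
#' "Peak2" (12:00-17:59) and "Low" (18:00-05:59); the three periods partition
#' the 24 hours into 6 + 6 + 12.
#'
#' @param hour integer hour(s) of day, 0-23.
#' @return factor with levels Low, Peak1, Peak2.
#' @examples
#' assign_period(c(6, 12, 18, 0))
#' @export
assign_period <- function(hour) {
  pf_check(all(!is.na(hour)) && all(hour %in% 0:23), "'hour' must lie in 0..23")
  factor(ifelse(hour >= 6 & hour < 12, "Peak1",
                ifelse(hour >= 12 & hour < 18, "Peak2", "Low")),
         levels = period_levels)
}

## shared data prep for the period model
period_model_frame <- function(data, response) {
  d <- data[!is.na(data[[response]]), , drop = FALSE]
  d$y <- sqrt(d[[response]])
  d$period <- assign_period(d$hour)
  d$week <- (d$day - 1) %/% 7 + 1
  d$cweek <- d$week - 1 # week 1 -> 0, intercepts are week-1 values
  d$pen <- factor(d$pen_id)
  d$dayf <- factor(d$day)
  if ("batch" %in% names(d)) d$batchf <- factor(d$batch)
  for (tr in c("tail", "straw", "stock")) if (tr %in% names(d)) d[[tr]] <- factor(d[[tr]])
  d
}

#' Fit the time-period by week by treatment model
#'
#' Models the square root of an hourly response with fixed effects for time
#' period, week (continuous, centred so intercepts are week-1 values), the
#' three pen treatments, the period-by-week interaction, and the two- and
#' three-way interactions of period and week with each treatment. Random
#' intercepts for pen and day-within-pen (batch as an outer level when
#' present) with AR(1) correlation between adjacent hours within a pen-day,
#' via [nlme::lme()]. With `select = TRUE` the fixed structure is reduced by
#' stepwise backward elimination using ML likelihood-ratio tests at level
#' `alpha` (marginality respected), then refit by REML.
#'
#' @param data cleaned pen-level hourly table carrying treatments.
#' @param response `"water"` or `"activations"`.
#' @param alpha significance level for elimination.
#' @param select run backward elimination (default) or fit the full model.
#' @param keep_model keep the underlying `lme` object.
#' @return object of class `period_fit`: fixed-effect table, retained terms,
#'   elimination log, variance components, AR(1) `rho`, and everything needed
#'   by [period_contrasts()].
#' @export
fit_period_model <- function(data, response = c("water", "activations"),
                             alpha = 0.05, select = TRUE, keep_model = FALSE) {
  response <- match.arg(response)
  d <- period_model_frame(data, response)
  treatments <- c("tail", "straw", "stock")
  treatments <- treatments[vapply(treatments, function(tr)
    tr %in% names(d) && nlevels(droplevels(d[[tr]])) > 1, logical(1))]
  full_terms <- c("period", "cweek", treatments, "period:cweek",
                  unlist(lapply(treatments, function(tr)
                    paste(c("period", "cweek", "period:cweek"), tr, sep = ":"))))
  multi_batch <- "batchf" %in% names(d) && nlevels(droplevels(d$batchf)) > 1
  grp <- if (multi_batch) "batchf/pen/dayf" else "pen/dayf"
  random <- as.formula(paste("~ 1 |", grp))
  ar_form <- as.formula(paste("~ hour |", grp))

  if (select) {
    sel <- backward_eliminate("y", full_terms, d, random, ar_form, alpha)
    retained <- sel$retained
    elim_log <- sel$log
  } else {
    retained <- full_terms
    elim_log <- NULL
  }
  if (!length(retained)) retained <- "1"
  fml <- as.formula(paste("y ~", paste(retained, collapse = " + ")))
  fit <- tryCatch(
    lme_robust(fml, data = d, random = random, ar_form = ar_form,
               method = "REML"),
    error = function(e) pf_stop("period model did not converge: ", conditionMessage(e)))
  vc <- suppressWarnings(as.numeric(nlme::VarCorr(fit)[, "StdDev"]))
  vc <- vc[!is.na(vc)]
  names(vc) <- c(strsplit(grp, "/")[[1]], "residual")
  margins <- if (length(treatments))
    prop.table(table(unique(d[c("pen_id", treatments)])[treatments])) else NULL
  structure(list(
    response = response, retained = retained, elim_log = elim_log,
    fixef = nlme::fixef(fit), vcov = as.matrix(fit$varFix),
    se = sqrt(diag(as.matrix(fit$varFix))),
    varcomp = vc, rho = unname(coef(fit$modelStruct$corStruct, unconstrained = FALSE)),
    formula = paste(deparse(fml), collapse = ""),
    xlev = lapply(d[c("period", treatments)], levels),
    treatments = treatments, margins = margins,
    n = nrow(d), weeks = range(d$week), alpha = alpha,
    logLik = as.numeric(logLik(fit)),
    model = if (keep_model) fit else NULL
  ), class = "period_fit")
}

#' @export
print.period_fit <- function(x, ...) {
  cat("Period x week x treatment model of sqrt(", x$response, ")\n", sep = "")
  cat("  retained terms:", paste(x$retained, collapse = ", "), "\n")
  if (!is.null(x$elim_log) && nrow(x$elim_log)) {
    cat("  elimination log:\n")
    print(x$elim_log, row.names = FALSE, digits = 4)
  }
  cat(sprintf("  AR(1) rho = %.3f; SDs: %s\n", x$rho,
              paste(names(x$varcomp), round(x$varcomp, 4), collapse = ", ")))
  invisible(x)
}

## model matrix rows for a (period, stock, tail, straw) grid at a given cweek,
## marginalized over the pen-level distribution of the non-focus treatments
period_design_row <- function(fit, period, cweek, fixed = list()) {
  grid <- list(period = factor(period, levels = fit$xlev$period), cweek = cweek)
  cells <- if (is.null(fit$margins)) data.frame(w = 1) else {
    cc <- as.data.frame(fit$margins, stringsAsFactors = FALSE)
    names(cc)[ncol(cc)] <- "w"
    cc
  }
  for (tr in names(fixed)) {
    if (tr %in% names(cells)) cells <- cells[cells[[tr]] == fixed[[tr]], , drop = FALSE]
    else cells[[tr]] <- fixed[[tr]]
  }
  cells$w <- cells$w / sum(cells$w)
  rhs <- as.formula(paste("~", sub("^.*~", "", fit$formula)))
  Xagg <- 0
  for (r in seq_len(nrow(cells))) {
    df <- data.frame(period = grid$period, cweek = grid$cweek)
    for (tr in fit$treatments)
      df[[tr]] <- factor(cells[[tr]][r], levels = fit$xlev[[tr]])
    X <- model.matrix(rhs, df)
    Xagg <- Xagg + cells$w[r] * X
  }
  Xagg
}

#' Back-transformed period means and treatment contrasts
#'
#' Computes marginal sqrt-scale period means at a given week (other
#' treatments averaged over their pen-level distribution), back-transforms
#' them by squaring, and forms the low-minus-high stocking-density difference
#' per period with delta-method standard errors.
#'
#' @param fit a `period_fit`.
#' @param at_week week at which to evaluate (default 5, mid-study).
#' @param treatment the treatment to contrast (only `"stock"` is meaningful
#'   in this design). Requesting a contrast whose terms were all eliminated
#'   is an error.
#' @return list with `means` (per-period marginal means) and `diffs`
#'   (per-period back-transformed treatment differences with SEs).
#' @export
period_contrasts <- function(fit, at_week = 5, treatment = "stock") {
  pf_check(inherits(fit, "period_fit"), "'fit' must be a period_fit")
  has_term <- any(vapply(fit$retained, function(tm)
    treatment %in% term_factors(tm), logical(1)))
  if (!has_term)
    pf_stop("treatment '", treatment, "' was eliminated from the model; ",
            "no contrast is available")
  cw <- at_week - 1
  levs <- fit$xlev[[treatment]]
  pf_check(length(levs) == 2, "contrast requires a two-level treatment")
  means <- lapply(fit$xlev$period, function(p) {
    X <- period_design_row(fit, p, cw)
    m <- drop(X %*% fit$fixef)
    v <- drop(X %*% fit$vcov %*% t(X))
    data.frame(period = p, week = at_week, sqrt_mean = m, se_sqrt = sqrt(v),
               bt_mean = m^2, se_bt = 2 * abs(m) * sqrt(v))
  })
  diffs <- lapply(fit$xlev$period, function(p) {
    Xh <- period_design_row(fit, p, cw, setNames(list(levs[1]), treatment))
    Xl <- period_design_row(fit, p, cw, setNames(list(levs[2]), treatment))
    mh <- drop(Xh %*% fit$fixef); ml <- drop(Xl %*% fit$fixef)
    ## gradient of ml^2 - mh^2 w.r.t. beta
    g <- 2 * ml * Xl - 2 * mh * Xh
    se <- sqrt(drop(g %*% fit$vcov %*% t(g)))
    data.frame(period = p, week = at_week,
               level_ref = levs[1], level_alt = levs[2],
               bt_ref = mh^2, bt_alt = ml^2,
               diff_bt = ml^2 - mh^2, se_diff_bt = se)
  })
  list(means = do.call(rbind, means), diffs = do.call(rbind, diffs))
}

#' Share of use in the Low period, compared between groups
#'
#' For each pen, the share of its total (post-cleaning) use falling in the
#' Low period (18:00-05:59), compared between the two levels of a grouping
#' treatment with a two-sided Mann-Whitney U test (exact when both groups
#' have <= 25 pens and no ties; normal approximation with continuity and tie
#' correction otherwise).
#'
#' @param data cleaned pen-level hourly table.
#' @param group grouping column (default `"stock"`).
#' @param response `"water"` or `"activations"`.
#' @return list: per-pen `shares`, group `medians`, `statistic`, `p.value`,
#'   `method`.
#' @export
low_period_share_test <- function(data, group = "stock",
                                  response = c("water", "activations")) {
  response <- match.arg(response)
  sh <- period_shares(data, response)
  g <- data[[group]][match(sh$pen_id, data$pen_id)]
  sh$group <- droplevels(factor(g))
  pf_check(nlevels(sh$group) == 2, "'group' must have exactly two levels present")
  ns <- table(sh$group)
  pf_check(all(ns >= 2), "each group needs at least 2 pens")
  x <- sh$share_low[sh$group == levels(sh$group)[1]]
  y <- sh$share_low[sh$group == levels(sh$group)[2]]
  tst <- mw_test(x, y)
  list(shares = sh,
       medians = setNames(c(median(x), median(y)), levels(sh$group)),
       statistic = unname(tst$statistic), p.value = tst$p.value,
       method = tst$method, group = group, response = response)
}

## per-pen shares of the three periods (sum to 1 per pen over observed hours)
period_shares <- function(data, response) {
  d <- data[!is.na(data[[response]]), , drop = FALSE]
  per <- assign_period(d$hour)
  tot <- rowsum(d[[response]], d$pen_id)
  out <- data.frame(pen_id = rownames(tot))
  for (pl in period_levels) {
    s <- rowsum(d[[response]] * (per == pl), d$pen_id)
    out[[paste0("share_", tolower(pl))]] <- s[match(out$pen_id, rownames(s))] / tot[, 1]
  }
  out
}

## Mann-Whitney with the documented exactness rule
mw_test <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && max(length(x), length(y)) <= 25
  suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
}
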
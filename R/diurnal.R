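#' Harmonic (cosinor) design matrix
#'
#' Linearizes the sum-of-waves mean function: each wave
#' `A * sin(b*t + c)` with fixed angular frequency `b_i = i*2*pi/24` becomes
#' `u * sin(b_i t) + v * cos(b_i t)` with `u = A cos(c)`, `v = A sin(c)`.
#' Columns: intercept, day, sin/cos per wave, and day-by-sin/cos interactions
#' (so amplitudes may evolve with age). `t` is the integer hour of day 0-23
#' evaluated at hour start.
#'
#' @param rows data.frame with `day` and `hour`.
#' @param n_waves number of waves (>= 1; default 3 = 24/12/8-h cycles).
#' @return numeric matrix with `2 + 4 * n_waves` named columns.
#' @export
build_harmonic_design <- function(rows, n_waves = 3) {
  pf_check(is.numeric(n_waves) && n_waves >= 1, "'n_waves' must be >= 1")
  pf_check(all(c("day", "hour") %in% names(rows)), "'rows' must carry day and hour")
  n <- nrow(rows)
  X <- matrix(NA_real_, n, 2 + 4 * n_waves)
  X[, 1] <- 1
  X[, 2] <- rows$day
  nm <- c("(Intercept)", "day")
  for (i in seq_len(n_waves)) {
    b <- i * 2 * pi / 24
    s <- sin(b * rows$hour); cc <- cos(b * rows$hour)
    X[, 2 + 4 * (i - 1) + 1:4] <- cbind(s, cc, rows$day * s, rows$day * cc)
    nm <- c(nm, paste0(c("sin", "cos", "day_sin", "day_cos"), i))
  }
  colnames(X) <- nm
  X
}

#' Convert between linear wave coefficients and amplitude/phase
#'
#' `amplitude_phase()` maps sine/cosine coefficients `(u, v)` to the
#' canonical amplitude/phase pair: `A = sqrt(u^2 + v^2) >= 0`,
#' `c = atan2(v, u)` in `(-pi, pi]`. `phase_coeffs()` is the inverse,
#' `u = A cos(c)`, `v = A sin(c)`; the round trip is the identity.
#' `canonical_wave()` maps any (possibly negative-amplitude) pair to the
#' canonical form `(|A|, c + pi)` wrapped to `(-pi, pi]`. A zero amplitude
#' reports phase 0 by convention.
#'
#' @param u,v linear coefficients of `sin(bt)` and `cos(bt)`.
#' @param A,c amplitude and phase (radians).
#' @return a list with components `A` and `c` (or `u` and `v`), vectorized.
#' @examples
#' amplitude_phase(0, 1) # A = 1, c = pi/2
#' @export
amplitude_phase <- function(u, v) {
  A <- sqrt(u^2 + v^2)
  ph <- ifelse(A == 0, 0, atan2(v, u))
  list(A = A, c = wrap_angle(ph))
}

#' @rdname amplitude_phase
#' @export
phase_coeffs <- function(A, c) list(u = A * cos(c), v = A * sin(c))

#' @rdname amplitude_phase
#' @export
canonical_wave <- function(A, c) {
  flip <- A < 0
  list(A = abs(A), c = ifelse(A == 0, 0, wrap_angle(ifelse(flip, c + pi, c))))
}

#' Fit the square-root-scale harmonic mixed model
#'
#' Regresses the square root of an hourly response on the harmonic design
#' ([build_harmonic_design()]) with random intercepts for pen and
#' day-within-pen (batch added as an outer level when several batches are
#' present) and an AR(1) correlation between adjacent residual hours within
#' each pen-day. Estimated by REML via [nlme::lme()]. Fixed effects are
#' reported both as linear coefficients and in canonical amplitude/phase
#' form with delta-method standard errors.
#'
#' `method = "ols"` is the documented fixed-effect fallback: identical fixed
#' effects on balanced designs, naive SEs, no variance components. It is also
#' the exact route for noise-free input, where REML is degenerate;
#' `method = "auto"` (default) detects that case and otherwise falls back
#' with a warning only if the mixed fit fails.
#'
#' @param data cleaned pen-level hourly table (flagged cells `NA`).
#' @param response `"water"` or `"activations"`.
#' @param n_waves number of harmonic waves.
#' @param method `"auto"`, `"lme"` or `"ols"`.
#' @param keep_model keep the underlying `lme`/`lm` object (large).
#' @return an object of class `harmonic_fit`: `mu0`, `trend`, `waves`
#'   (amplitude/phase table with SEs and the linear u/v and day-interaction
#'   coefficients), `coef`, `se`, `vcov`, `varcomp` (SDs of the random
#'   intercepts and residual), `rho`, `n`, `logLik`, `converged`, `method`.
#' @export
fit_harmonic_mixed <- function(data, response = c("water", "activations"),
                               n_waves = 3, method = c("auto", "lme", "ols"),
                               keep_model = FALSE) {
  response <- match.arg(response)
  method <- match.arg(method)
  pf_check(length(unique(data$day)) >= 2 && length(unique(data$pen_id)) >= 2,
           "need data spanning at least 2 days and 2 pens")
  d <- data[!is.na(data[[response]]), , drop = FALSE]
  d$y <- sqrt(d[[response]])
  X <- build_harmonic_design(d, n_waves)
  for (j in seq_len(ncol(X))[-1]) d[[paste0("x", j)]] <- X[, j]
  xn <- paste0("x", seq_len(ncol(X))[-1])
  fml <- as.formula(paste("y ~", paste(xn, collapse = " + ")))
  d$pen <- factor(d$pen_id)
  d$dayf <- factor(d$day)
  multi_batch <- "batch" %in% names(d) && length(unique(d$batch)) > 1
  if (multi_batch) d$batchf <- factor(d$batch)
  grp <- if (multi_batch) "batchf/pen/dayf" else "pen/dayf"

  ols_fit <- function(note) {
    fit <- lm(fml, data = d)
    ## suppressed: "essentially perfect fit" is expected on noise-free input
    V <- suppressWarnings(vcov(fit))
    list(coef = setNames(coef(fit), colnames(X)),
         vcov = structure(V, dimnames = list(colnames(X), colnames(X))),
         varcomp = c(residual = sqrt(sum(residuals(fit)^2) /
                                       max(1, fit$df.residual))),
         rho = NA_real_,
         logLik = as.numeric(logLik(fit)), converged = TRUE,
         method = "ols", note = note, model = fit)
  }
  ## noise-free input: OLS is exact, REML is degenerate
  resid_var <- var(residuals(lm.fit(X, d$y)))
  res <- if (method == "ols" || (method == "auto" && resid_var < 1e-16)) {
    ols_fit(if (method != "ols") "noise-free input: exact OLS solution" else NULL)
  } else {
    lme_try <- tryCatch({
      fit <- lme_robust(fml, data = d, random = as.formula(paste("~ 1 |", grp)),
                        ar_form = as.formula(paste("~ hour |", grp)),
                        method = "REML")
      vc <- suppressWarnings(as.numeric(nlme::VarCorr(fit)[, "StdDev"]))
      vc <- vc[!is.na(vc)]
      names(vc) <- c(strsplit(grp, "/")[[1]], "residual")
      list(coef = setNames(nlme::fixef(fit), colnames(X)),
           vcov = structure(as.matrix(fit$varFix), dimnames = list(colnames(X), colnames(X))),
           varcomp = vc,
           rho = unname(coef(fit$modelStruct$corStruct, unconstrained = FALSE)),
           logLik = as.numeric(logLik(fit)), converged = TRUE,
           method = "lme", note = NULL, model = fit)
    }, error = function(e) e)
    if (inherits(lme_try, "error")) {
      if (method == "lme")
        pf_stop("mixed model did not converge: ", conditionMessage(lme_try))
      warning("mixed estimation failed (", conditionMessage(lme_try),
              "); falling back to the OLS fixed-effect route")
      ols_fit(paste("lme failed:", conditionMessage(lme_try)))
    } else lme_try
  }

  se <- sqrt(diag(res$vcov))
  waves <- harmonic_waves_table(res$coef, res$vcov, n_waves)
  out <- structure(list(
    response = response, method = res$method, note = res$note,
    n = nrow(d), n_pens = length(unique(d$pen_id)),
    day_range = range(d$day), n_waves = n_waves,
    coef = res$coef, se = se, vcov = res$vcov,
    mu0 = unname(res$coef["(Intercept)"]), trend = unname(res$coef["day"]),
    waves = waves, varcomp = res$varcomp, rho = res$rho,
    logLik = res$logLik, converged = res$converged,
    model = if (keep_model) res$model else NULL
  ), class = "harmonic_fit")
  out
}

## Canonical amplitude/phase table with delta-method SEs from the linear fit.
harmonic_waves_table <- function(coef, V, n_waves) {
  rows <- lapply(seq_len(n_waves), function(i) {
    un <- paste0("sin", i); vn <- paste0("cos", i)
    u <- coef[[un]]; v <- coef[[vn]]
    ap <- amplitude_phase(u, v)
    Vi <- V[c(un, vn), c(un, vn)]
    gA <- c(u, v) / ap$A
    gC <- c(-v, u) / ap$A^2
    data.frame(wave = i, A = ap$A, b = i * 2 * pi / 24, c = ap$c,
               se_A = sqrt(drop(t(gA) %*% Vi %*% gA)),
               se_c = sqrt(drop(t(gC) %*% Vi %*% gC)),
               u = u, v = v,
               du = coef[[paste0("day_sin", i)]], dv = coef[[paste0("day_cos", i)]])
  })
  do.call(rbind, rows)
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("Harmonic mixed model of sqrt(", x$response, ") [", x$method, "]\n", sep = "")
  cat(sprintf("  n = %d hours, %d pens, days %d-%d\n", x$n, x$n_pens,
              x$day_range[1], x$day_range[2]))
  cat(sprintf("  initial mean %.4f (se %.4f), daily trend %.6f (se %.6f)\n",
              x$mu0, x$se["(Intercept)"], x$trend, x$se["day"]))
  w <- x$waves
  for (i in seq_len(nrow(w)))
    cat(sprintf("  wave %d (%d-h): A = %.4f (se %.4f), c = %.3f (se %.3f)\n",
                w$wave[i], 24 %/% w$wave[i], w$A[i], w$se_A[i], w$c[i], w$se_c[i]))
  if (!is.na(x$rho))
    cat(sprintf("  AR(1) rho = %.3f; SDs: %s\n", x$rho,
                paste(names(x$varcomp), round(x$varcomp, 4), collapse = ", ")))
  invisible(x)
}

#' Model-estimated diurnal curve
#'
#' Back-transformed expected hourly use on a given study day: the sqrt-scale
#' mean function evaluated per hour, clipped at zero and squared.
#'
#' @param fit a `harmonic_fit`.
#' @param day study day (warns outside the fitted range but still computes).
#' @param hours hours of day to evaluate.
#' @return data.frame with `hour`, `sqrt_mean`, `expected` (original scale).
#' @export
predict_diurnal <- function(fit, day, hours = 0:23) {
  pf_check(inherits(fit, "harmonic_fit"), "'fit' must be a harmonic_fit")
  if (day < fit$day_range[1] || day > fit$day_range[2])
    warning("day ", day, " lies outside the fitted range [",
            fit$day_range[1], ", ", fit$day_range[2], "]")
  m <- fit$mu0 + fit$trend * day
  for (i in seq_len(nrow(fit$waves))) {
    w <- fit$waves[i, ]
    m <- m + (w$u + w$du * day) * sin(w$b * hours) + (w$v + w$dv * day) * cos(w$b * hours)
  }
  data.frame(hour = hours, sqrt_mean = m, expected = pmax(m, 0)^2)
}

#' Per-pig daily total from a harmonic fit
#'
#' Sum of the back-transformed diurnal curve over the 24 hours of a study
#' day. With `variance_correction = TRUE` the expectation of the squared
#' observation adds the total sqrt-scale variance (residual plus random
#' intercepts) per hour before summation; off by default so the value matches
#' the plain back-transformed curve.
#'
#' @inheritParams predict_diurnal
#' @param variance_correction add per-hour variance to the expectation.
#' @return expected litres (or activations) per pig for that day.
#' @export
daily_total <- function(fit, day, variance_correction = FALSE) {
  pd <- predict_diurnal(fit, day, 0:23)
  tot <- sum(pd$expected)
  if (variance_correction) {
    v <- sum(fit$varcomp[!is.na(fit$varcomp)]^2)
    tot <- tot + 24 * v
  }
  tot
}
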
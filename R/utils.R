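#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.formula coef fitted lm logLik median model.matrix
#'   pchisq predict quantile rbeta residuals rnorm runif sd setNames terms
#'   var vcov kruskal.test wilcox.test anova update rbinom
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

pf_stop <- function(...) stop(..., call. = FALSE)

pf_check <- function(cond, ...) if (!isTRUE(cond)) pf_stop(...)

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded generator calls do not perturb the session
#' stream. A `NULL` seed leaves the RNG untouched.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  pf_check(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
           "'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Wrap an angle to the canonical interval (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

## Stationary AR(1) innovations: matrix len x n_groups flattened column-wise,
## marginal SD `sd`, lag-1 correlation `rho` within each column.
ar1_noise <- function(n_groups, len, rho, sd) {
  z <- matrix(rnorm(n_groups * len), nrow = len)
  if (rho != 0 && len > 1L) {
    e <- z
    for (t in 2:len) e[t, ] <- rho * e[t - 1L, ] + sqrt(1 - rho^2) * z[t, ]
    z <- e
  }
  as.vector(z) * sd
}

## Solve for the sqrt-scale shift d with (m + d)^2 - m^2 = delta (one-sided
## case/control offsets). Used where a back-transformed difference is stated.
sqrt_shift_onesided <- function(delta, m) sqrt(m^2 + delta) - m

## Symmetric sqrt-scale shift: low = m + d/2, high = m - d/2 gives a
## back-transformed marginal difference of exactly 2 m d = delta.
sqrt_shift_symmetric <- function(delta, m) delta / (2 * m)

## lme with an AR(1) fitting cascade. corAR1 under nlminb, then optim, can
## both stray into a singular region when rho approaches 1 on a gappy hour
## lattice; the last resort refits with the continuous-time corCAR1 (equal to
## corAR1 with rho > 0 on an integer lattice) accepting boundary convergence,
## and reports that with a warning. Errors only if everything fails.
lme_robust <- function(fixed, data, random, ar_form, method) {
  attempts <- list(
    list(corr = nlme::corAR1(form = ar_form), ctl = nlme::lmeControl(), note = NULL),
    list(corr = nlme::corAR1(form = ar_form), ctl = nlme::lmeControl(opt = "optim"),
         note = NULL),
    list(corr = nlme::corCAR1(form = ar_form),
         ctl = nlme::lmeControl(returnObject = TRUE),
         note = paste("AR(1) fit was numerically fragile; refit with the",
                      "equivalent continuous-time corCAR1, accepting boundary",
                      "convergence"))
  )
  err <- NULL
  for (a in attempts) {
    fit <- tryCatch(
      suppressWarnings(
        nlme::lme(fixed, data = data, random = random, correlation = a$corr,
                  method = method, control = a$ctl)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      if (!is.null(a$note)) warning(a$note)
      return(fit)
    }
    err <- fit
  }
  stop(err)
}

## Hour-of-day -> time period used throughout ("Low" 18:00-05:59,
## "Peak1" 06:00-11:59, "Peak2" 12:00-17:59).
period_levels <- c("Low", "Peak1", "Peak2")
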
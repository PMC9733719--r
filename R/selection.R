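## Stepwise backward elimination for lme fixed effects via ML likelihood-ratio
## tests. Marginality is respected: a term is only removable while no retained
## higher-order term contains it. The least significant admissible term
## (largest LRT p, ties broken deterministically by term label) is dropped
## while its p >= alpha. Returns the retained terms and an elimination log;
## the caller refits by REML for final estimates.

term_factors <- function(term) sort(strsplit(term, ":", fixed = TRUE)[[1]])

## terms with no retained strict superset
admissible_terms <- function(retained) {
  fl <- lapply(retained, term_factors)
  keep <- vapply(seq_along(retained), function(i) {
    !any(vapply(seq_along(retained), function(j) {
      j != i && all(fl[[i]] %in% fl[[j]])
    }, logical(1)))
  }, logical(1))
  retained[keep]
}

backward_eliminate <- function(response_var, full_terms, data, random,
                               ar_form, alpha = 0.05) {
  fit_ml <- function(terms) {
    fml <- as.formula(paste(response_var, "~", paste(terms, collapse = " + ")))
    lme_robust(fml, data = data, random = random, ar_form = ar_form,
               method = "ML")
  }
  retained <- sort(full_terms)
  current <- fit_ml(retained)
  log_rows <- list()
  repeat {
    adm <- sort(admissible_terms(retained))
    if (!length(adm)) break
    tests <- lapply(adm, function(tm) {
      red <- tryCatch(fit_ml(setdiff(retained, tm)), error = function(e) e)
      if (inherits(red, "error"))
        return(list(p = 0, chisq = NA_real_, df = NA_real_, red = NULL,
                    note = paste("reduced fit failed:", conditionMessage(red))))
      chisq <- max(0, 2 * (as.numeric(logLik(current)) - as.numeric(logLik(red))))
      df <- attr(logLik(current), "df") - attr(logLik(red), "df")
      list(p = pchisq(chisq, df, lower.tail = FALSE), chisq = chisq, df = df,
           red = red, note = NA_character_)
    })
    ps <- vapply(tests, `[[`, numeric(1), "p")
    imax <- which.max(ps) # ties: first in sorted term order
    if (ps[imax] >= alpha && !is.null(tests[[imax]]$red)) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        term = adm[imax], chisq = tests[[imax]]$chisq, df = tests[[imax]]$df,
        p = ps[imax], action = "dropped")
      retained <- setdiff(retained, adm[imax])
      current <- tests[[imax]]$red
      if (!length(retained)) break
    } else {
      for (ii in seq_along(adm))
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          term = adm[ii], chisq = tests[[ii]]$chisq, df = tests[[ii]]$df,
          p = ps[ii], action = "retained")
      break
    }
  }
  list(retained = retained,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(term = character(0), chisq = numeric(0), df = numeric(0),
                    p = numeric(0), action = character(0)))
}
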
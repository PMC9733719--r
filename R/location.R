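#' Per-pen mean use of each drinking-cup location
#'
#' Aggregates cleaned sensor-level hours to one observation per pen and cup
#' location: the mean over all observed hours of water use and activation
#' frequency. Pens missing one of the two locations are excluded with a
#' message.
#'
#' @param sensor_hourly cleaned sensor-level hourly table.
#' @return data.frame, one row per pen: `pen_id`, `batch`, `stock`,
#'   `water_F`, `water_OF`, `act_F`, `act_OF`, `n_hours`.
#' @export
location_means <- function(sensor_hourly) {
  pf_check(all(c("pen_id", "location", "water", "activations") %in% names(sensor_hourly)),
           "'sensor_hourly' must be a sensor-level table")
  x <- sensor_hourly
  locs <- tapply(x$location, x$pen_id, function(l) length(unique(l)))
  bad <- names(locs)[locs < 2]
  if (length(bad)) {
    message("excluding pen(s) missing a cup location: ", paste(bad, collapse = ", "))
    x <- x[!(x$pen_id %in% bad), , drop = FALSE]
  }
  agg <- function(col, loc) {
    xx <- x[x$location == loc, , drop = FALSE]
    m <- tapply(xx[[col]], xx$pen_id, mean, na.rm = TRUE)
    m
  }
  pens <- sort(unique(x$pen_id))
  meta <- x[match(pens, x$pen_id), intersect(c("pen_id", "batch", "stock"), names(x)),
            drop = FALSE]
  out <- data.frame(meta,
                    water_F = agg("water", "F")[pens],
                    water_OF = agg("water", "OF")[pens],
                    act_F = agg("activations", "F")[pens],
                    act_OF = agg("activations", "OF")[pens],
                    n_hours = tapply(!is.na(x$water), x$pen_id, sum)[pens],
                    row.names = NULL)
  out
}

#' Paired comparison of the two cup locations
#'
#' Two-sided Wilcoxon signed-rank test on the per-pen differences (F - OF)
#' from [location_means()]. Zero differences are dropped; the null
#' distribution is exact for <= 25 non-zero pairs without ties and a normal
#' approximation with continuity correction otherwise. If every difference is
#' zero the test is degenerate and reported with `p.value = NA`.
#'
#' @param summaries output of [location_means()].
#' @param response `"water"` or `"activations"`.
#' @param subset optional logical vector (length `nrow(summaries)`) or a
#'   named list of column filters, e.g. `list(batch = 1)`.
#' @return list: `n`, `mean_F`, `mean_OF`, `mean_diff`, `statistic`,
#'   `p.value`, `method`.
#' @export
paired_location_test <- function(summaries, response = c("water", "activations"),
                                 subset = NULL) {
  response <- match.arg(response)
  s <- summaries
  if (!is.null(subset)) {
    keep <- if (is.logical(subset)) subset else {
      k <- rep(TRUE, nrow(s))
      for (nm in names(subset)) k <- k & (s[[nm]] %in% subset[[nm]])
      k
    }
    s <- s[keep, , drop = FALSE]
  }
  pf_check(nrow(s) >= 2, "need at least 2 paired pens")
  cols <- if (response == "water") c("water_F", "water_OF") else c("act_F", "act_OF")
  f <- s[[cols[1]]]; o <- s[[cols[2]]]
  d <- f - o
  nz <- d[d != 0]
  res <- list(n = nrow(s), mean_F = mean(f), mean_OF = mean(o), mean_diff = mean(d))
  if (!length(nz)) {
    res$statistic <- NA_real_; res$p.value <- NA_real_
    res$method <- "degenerate: all paired differences are zero"
    return(res)
  }
  ties <- anyDuplicated(abs(nz)) > 0
  exact <- !ties && length(nz) <= 25
  tst <- suppressWarnings(wilcox.test(f, o, paired = TRUE, exact = exact, correct = TRUE))
  res$statistic <- unname(tst$statistic)
  res$p.value <- tst$p.value
  res$method <- tst$method
  res
}

#' Location comparison table across batches and stocking densities
#'
#' Convenience wrapper reproducing the standard reporting layout: the paired
#' F-vs-OF test across all pens, within each batch, and within each stocking
#' density, for one response.
#'
#' @inheritParams paired_location_test
#' @return data.frame with one row per subset: n, mean F, mean OF, mean
#'   difference and p-value.
#' @export
location_table <- function(summaries, response = c("water", "activations")) {
  response <- match.arg(response)
  row_for <- function(label, subset) {
    t <- paired_location_test(summaries, response, subset)
    data.frame(subset = label, n = t$n, mean_F = t$mean_F, mean_OF = t$mean_OF,
               diff = t$mean_diff, p.value = t$p.value)
  }
  rows <- list(row_for("all", NULL))
  if ("batch" %in% names(summaries))
    for (b in sort(unique(summaries$batch)))
      rows[[length(rows) + 1L]] <- row_for(paste("batch", b), list(batch = b))
  if ("stock" %in% names(summaries))
    for (k in levels(factor(summaries$stock)))
      rows[[length(rows) + 1L]] <- row_for(paste("stock", k), list(stock = k))
  do.call(rbind, rows)
}
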
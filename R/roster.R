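#' Generate a balanced pen roster
#'
#' Builds pen metadata for a 2 x 2 x 2 factorial of tail docking (TAIL),
#' straw provision (STRAW) and stocking density (STOCK), replicated
#' `n_per_combination` times within each of `batches` batches. Stocking
#' density determines the pig count: high = 0.73 m2/pig with 18 pigs,
#' low = 1.21 m2/pig with 11 pigs. Physical room positions 1..N are assigned
#' at random within each batch (used for proximity matching of case-control
#' pairs).
#'
#' @param n_per_combination replicates of each of the 8 treatment
#'   combinations per batch (>= 1).
#' @param batches number of batches (>= 1).
#' @param seed optional integer seed; the same seed reproduces the roster
#'   exactly.
#' @return a `data.frame` with one row per pen: `pen_id`, `batch`, `tail`
#'   (docked/undocked), `straw` (with/without), `stock` (high/low), `n_pigs`,
#'   `position`.
#' @examples
#' r <- generate_pen_roster(1, 1, seed = 1)
#' nrow(r) # 8, one pen per treatment combination
#' @export
generate_pen_roster <- function(n_per_combination = 7, batches = 1, seed = NULL) {
  pf_check(is.numeric(n_per_combination) && length(n_per_combination) == 1 &&
             n_per_combination >= 1 && n_per_combination == round(n_per_combination),
           "'n_per_combination' must be a positive integer")
  pf_check(is.numeric(batches) && length(batches) == 1 && batches >= 1 &&
             batches == round(batches), "'batches' must be a positive integer")
  with_local_seed(seed, {
    out <- lapply(seq_len(batches), function(b) {
      roster_batch(b, rep(n_per_combination, 8L))
    })
    do.call(rbind, out)
  })
}

## One batch with per-combination replicate counts (length-8 vector ordered
## as expand.grid(tail, straw, stock)). Positions shuffled within the batch.
roster_batch <- function(batch, reps) {
  combos <- expand.grid(tail = c("docked", "undocked"),
                        straw = c("with", "without"),
                        stock = c("high", "low"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- rep(seq_len(8L), times = reps)
  n <- length(idx)
  pos <- sample.int(n)
  df <- data.frame(
    pen_id = sprintf("B%dP%02d", batch, seq_len(n)),
    batch = batch,
    tail = factor(combos$tail[idx], levels = c("docked", "undocked")),
    straw = factor(combos$straw[idx], levels = c("without", "with")),
    stock = factor(combos$stock[idx], levels = c("high", "low")),
    stringsAsFactors = FALSE
  )
  df$n_pigs <- ifelse(df$stock == "high", 18L, 11L)
  df$position <- pos
  df
}

#' Pen roster at the scale of the original study
#'
#' 112 pens across four batches: batches 1, 3 and 4 with four pens per
#' treatment combination (32 pens each) and a reduced batch 2 with three
#' pens per docked combination and one per undocked combination (16 pens),
#' reflecting a smaller intake of undocked pigs in that batch.
#'
#' @param seed optional integer seed.
#' @return a pen roster `data.frame` (see [generate_pen_roster()]).
#' @export
roster_study_scale <- function(seed = NULL) {
  with_local_seed(seed, {
    b134 <- lapply(c(1L, 3L, 4L), function(b) roster_batch(b, rep(4L, 8L)))
    ## combos ordered tail fastest: docked rows are 1,3,5,7
    reps2 <- ifelse(expand.grid(t = 1:2, s = 1:2, k = 1:2)$t == 1L, 3L, 1L)
    b2 <- roster_batch(2L, reps2)
    out <- rbind(b134[[1]], b2, b134[[2]], b134[[3]])
    rownames(out) <- NULL
    out
  })
}
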
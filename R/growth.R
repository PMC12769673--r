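#' Population doublings between two cell counts
#'
#' \code{(log(n_end) - log(n_start)) / log(2)}; negative values indicate net
#' cell loss. The log base cancels, natural log is used internally.
#'
#' @param n_start,n_end cell counts (> 0), vectorized.
#' @return number of population doublings.
#' @export
population_doubling <- function(n_start, n_end) {
  if (any(n_start <= 0) || any(n_end <= 0)) {
    stop_("cell counts must be positive")
  }
  (log(n_end) - log(n_start)) / log(2)
}

#' Cumulative population-doubling curve from passaging records
#'
#' Computes per-interval doublings from (seeded, harvested) count pairs and
#' their running sum, per condition and replicate.
#'
#' @param records data.frame with columns \code{time_days}, \code{condition},
#'   \code{replicate}, \code{seeded}, \code{harvested}; timepoints strictly
#'   increasing within each condition x replicate series.
#' @return the records with added \code{doublings} and
#'   \code{cumulative_doublings} columns.
#' @export
cumulative_doublings <- function(records) {
  need <- c("time_days", "condition", "replicate", "seeded", "harvested")
  if (!all(need %in% names(records))) {
    stop_("records lack columns: %s",
          paste(setdiff(need, names(records)), collapse = ", "))
  }
  key <- interaction(records$condition, records$replicate, drop = TRUE)
  out <- lapply(split(records, key), function(df) {
    if (is.unsorted(df$time_days, strictly = TRUE)) {
      stop_("timepoints not strictly increasing for %s replicate %s",
            df$condition[1], df$replicate[1])
    }
    df$doublings <- population_doubling(df$seeded, df$harvested)
    df$cumulative_doublings <- cumsum(df$doublings)
    df
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$condition, out$replicate, out$time_days), , drop = FALSE]
}

#' Infection efficiency from puromycin survival counts
#'
#' Fraction of cells surviving selection relative to the unselected plate at
#' the same virus volume. Values above 1 (counting noise) are clipped to 1
#' with a warning.
#'
#' @param survivors_with_puromycin cell count after selection.
#' @param survivors_without cell count without selection (> 0).
#' @return efficiency in [0, 1].
#' @export
infection_efficiency <- function(survivors_with_puromycin, survivors_without) {
  if (survivors_without <= 0) stop_("unselected count must be > 0")
  if (survivors_with_puromycin < 0) stop_("selected count must be >= 0")
  eff <- survivors_with_puromycin / survivors_without
  if (eff > 1) {
    warning("selected count exceeds unselected count; efficiency clipped to 1")
    eff <- 1
  }
  eff
}

#' Multiplicity of infection from infection efficiency
#'
#' Inverts the single-hit Poisson infection model
#' \code{eff = 1 - exp(-MOI)}, i.e. \code{MOI = -log(1 - eff)}. At 30-50%
#' efficiency this gives the MOI window [0.357, 0.693].
#'
#' @param eff infected fraction in [0, 1).
#' @return the Poisson-implied MOI.
#' @export
moi_from_efficiency <- function(eff) {
  if (any(eff < 0) || any(eff >= 1)) stop_("efficiency must lie in [0, 1)")
  -log(1 - eff)
}
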
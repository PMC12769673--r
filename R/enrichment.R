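#' Right-tailed Fisher's exact test on a 2x2 table
#'
#' Tests over-representation with the hypergeometric right tail:
#' \code{p = P(X >= a)} where X counts hits inside the set under fixed
#' margins. The odds ratio is the cross-product \code{(a d)/(b c)}, computed
#' with a Haldane 0.5 continuity correction on all cells whenever
#' \code{b c = 0}.
#'
#' @param a hits inside the set.
#' @param b hits outside the set.
#' @param c non-hits inside the set.
#' @param d non-hits outside the set.
#' @return list with \code{p} and \code{odds_ratio}.
#' @export
fisher_right <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop_("counts must be non-negative")
  # X ~ Hypergeometric(white = a + b hits, black = c + d non-hits, drawn = a + c)
  p <- stats::phyper(a - 1, m = a + b, n = c + d, k = a + c,
                     lower.tail = FALSE)
  orat <- if (b * c == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(p = p, odds_ratio = orat)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, order preserving. Thin validated wrapper over
#' \code{p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member symbols, tab separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors (unique members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop_("duplicate set names in %s", path)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Gene-set enrichment of a hit list by right-tailed Fisher tests
#'
#' Each set is intersected with the universe; sets retaining at least
#' \code{min_set_size} members are tested for over-representation of the
#' hits and the p-values are Benjamini-Hochberg adjusted across retained
#' sets. Results are sorted by p, ties by set name.
#'
#' @param hits character vector of hit genes (must lie in the universe).
#' @param universe character vector of all scored genes.
#' @param sets named list of gene sets (e.g. from \code{\link{read_gmt}}).
#' @param min_set_size smallest in-universe set tested.
#' @return data.frame with set name, the 2x2 counts (\code{hits_in_set},
#'   \code{hits_out}, \code{nonhits_in_set}, \code{nonhits_out}), set size,
#'   \code{odds_ratio}, \code{p}, \code{q}.
#' @export
enrich_sets <- function(hits, universe, sets, min_set_size = 3L) {
  universe <- unique(universe)
  hits <- unique(hits)
  stray <- setdiff(hits, universe)
  if (length(stray)) {
    stop_("hits outside universe: %s", paste(utils::head(stray, 5), collapse = ", "))
  }
  sets <- lapply(sets, intersect, universe)
  sets <- sets[lengths(sets) >= min_set_size]
  if (length(sets) == 0) stop_("no gene set retains %d members in the universe",
                               min_set_size)
  n_hit <- length(hits)
  n_uni <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    m <- sets[[nm]]
    a <- length(intersect(hits, m))
    b <- n_hit - a
    cc <- length(m) - a
    d <- n_uni - n_hit - cc
    fr <- fisher_right(a, b, cc, d)
    data.frame(set = nm, hits_in_set = a, hits_out = b,
               nonhits_in_set = cc, nonhits_out = d, set_size = length(m),
               odds_ratio = fr$odds_ratio, p = fr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}
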
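#' Tracer specification for [1,2-13C2]-glucose labeling
#'
#' @param labeled_positions glucose carbons carrying the label.
#' @param purity isotopic purity of the tracer (fraction of nominally
#'   labeled positions actually 13C).
#' @param p13 natural 13C abundance.
#' @return list of class \code{tracer_spec}.
#' @export
tracer_spec <- function(labeled_positions = c("C1", "C2"),
                        purity = 0.99, p13 = 0.0107) {
  if (purity <= 0 || purity > 1) stop_("purity must lie in (0, 1]")
  if (p13 < 0 || p13 >= 0.5) stop_("p13 must lie in [0, 0.5)")
  structure(list(labeled_positions = labeled_positions,
                 purity = purity, p13 = p13), class = "tracer_spec")
}

#' Natural-abundance / tracer-purity correction matrix
#'
#' Builds the (n+1) x (n+1) matrix M with \code{M[i+1, j+1]} = probability
#' that a molecule carrying j tracer-derived labels is observed at mass m+i.
#' Column j is the convolution of a Binomial(j, purity) for label retention
#' over the j labeled carbons with a Binomial(n - j, p13) for natural 13C
#' gains over the remaining carbons. Only carbon isotopes are modeled, so
#' columns sum to 1 (and in general to at most 1).
#'
#' @param n_carbons carbon count of the metabolite (>= 1).
#' @param p13 natural 13C abundance (default 0.0107).
#' @param purity tracer isotopic purity (default 1).
#' @return (n+1) x (n+1) numeric matrix.
#' @export
correction_matrix <- function(n_carbons, p13 = 0.0107, purity = 1) {
  if (n_carbons < 1) stop_("n_carbons must be >= 1")
  tracer_spec(purity = purity, p13 = p13)  # range validation
  n <- as.integer(n_carbons)
  M <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    keep <- stats::dbinom(0:j, j, purity)          # labels retained
    gain <- stats::dbinom(0:(n - j), n - j, p13)   # natural 13C gains
    col <- numeric(n + 1)                          # direct convolution
    for (k in seq_along(keep)) {
      idx <- (k - 1) + seq_along(gain)
      col[idx] <- col[idx] + keep[k] * gain
    }
    M[, j + 1] <- col
  }
  M
}

#' Correct a measured mass isotopomer distribution
#'
#' Recovers the tracer-derived label distribution from a measured MID by
#' solving \code{raw = M t} with non-negative least squares (negative
#' corrected fractions are inadmissible on noisy data), then renormalizing
#' to fractions summing to 1.
#'
#' @param raw measured intensity or fraction vector, length n_carbons + 1.
#' @param M correction matrix from \code{\link{correction_matrix}}.
#' @return list with \code{fractions} (corrected, sums to 1),
#'   \code{raw_total} (sum of input intensities) and \code{residual}
#'   (NNLS residual norm relative to the input norm).
#' @export
correct_mid <- function(raw, M) {
  if (length(raw) != nrow(M)) stop_("MID length does not match matrix")
  if (any(raw < 0)) stop_("negative intensities")
  total <- sum(raw)
  if (total == 0) stop_("all-zero MID vector")
  y <- raw / total
  fit <- pracma::lsqnonneg(M, y)
  t <- fit$x
  if (sum(t) == 0) stop_("correction produced an all-zero solution")
  list(fractions = t / sum(t), raw_total = total,
       residual = sqrt(sum((M %*% t - y)^2)) / sqrt(sum(y^2)))
}

#' Normalize isotopologue intensities to total metabolite intensity
#'
#' @param intensities non-negative vector m+0..m+n.
#' @return list with \code{fractions} (sum to 1) and \code{total} (pool
#'   size, the total sum of all masses).
#' @export
normalize_total <- function(intensities) {
  if (any(intensities < 0)) stop_("negative intensities")
  total <- sum(intensities)
  if (total == 0) stop_("zero total intensity")
  list(fractions = intensities / total, total = total)
}

#' Lactate m+1 / m+2 pentose-phosphate-pathway index
#'
#' With [1,2-13C2]-glucose, intact glycolysis yields m+2 lactate while
#' oxidative-PPP transit loses the labeled C1 as CO2 and yields m+1
#' lactate; the m+1/m+2 ratio therefore reports relative oxPPP activity
#' (ratio = f / (1 - f) for oxPPP flux fraction f under the single-pass
#' model).
#'
#' @param lactate_fractions corrected lactate MID fractions (length 4,
#'   3 carbons).
#' @return m+1 / m+2 ratio.
#' @export
ppp_index <- function(lactate_fractions) {
  if (length(lactate_fractions) != 4) {
    stop_("lactate has 3 carbons: expected an m+0..m+3 vector of length 4")
  }
  if (lactate_fractions[3] <= 0) {
    stop_("uninformative labeling: lactate m+2 fraction is zero")
  }
  lactate_fractions[2] / lactate_fractions[3]
}

#' Glucose-uptake index: G6P to glucose total-pool ratio
#'
#' @param g6p_total total glucose-6-phosphate intensity.
#' @param glucose_total total glucose intensity (> 0).
#' @return the pool-size ratio.
#' @export
uptake_index <- function(g6p_total, glucose_total) {
  if (glucose_total <= 0) stop_("glucose pool must be > 0")
  if (g6p_total < 0) stop_("negative G6P pool")
  g6p_total / glucose_total
}

#' Simulate [1,2-13C2]-glucose labeling of lactate, G6P and glucose
#'
#' Two-pathway single-pass mixing model: a fraction \code{f_ppp} of glucose
#' transits the oxidative PPP (losing labeled C1 as CO2 and yielding one
#' m+1 and one m+0 lactate equivalent), the remainder intact glycolysis
#' (one m+2 and one m+0 lactate), so tracer-label lactate fractions obey
#' \code{m1 / (m1 + m2) = f_ppp}. Glucose and G6P carry both tracer labels.
#' The true label distributions are convolved forward with the
#' natural-abundance / purity matrix; optional proportional measurement
#' noise is applied per intensity. Non-oxidative PPP recycling and exchange
#' fluxes are deliberately outside the model.
#'
#' @param f_ppp oxidative-PPP flux fraction in [0, 1].
#' @param tracer a \code{\link{tracer_spec}}.
#' @param uptake glucose uptake parameter: G6P pool = uptake * glucose pool.
#' @param glucose_pool total glucose intensity (arbitrary units).
#' @param noise_sd proportional (lognormal-free, Gaussian) noise SD; 0 = off.
#' @param n_replicates replicates to simulate.
#' @param seed integer seed.
#' @return data.frame with columns \code{replicate}, \code{metabolite},
#'   \code{n_carbons} and intensity columns \code{m0..m6} (NA beyond a
#'   metabolite's carbon count).
#' @export
simulate_labeling <- function(f_ppp, tracer = tracer_spec(), uptake = 0.5,
                              glucose_pool = 1e6, noise_sd = 0,
                              n_replicates = 1L, seed = 1L) {
  if (f_ppp < 0 || f_ppp > 1) stop_("f_ppp must lie in [0, 1]")
  M3 <- correction_matrix(3, tracer$p13, tracer$purity)
  M6 <- correction_matrix(6, tracer$p13, tracer$purity)
  # tracer-label distributions (index = number of tracer-derived labels)
  t_lac <- c(1, f_ppp, 1 - f_ppp, 0) / 2
  t_hex <- c(0, 0, 1, 0, 0, 0, 0)
  pools <- c(lactate = 2 * glucose_pool, g6p = uptake * glucose_pool,
             glucose = glucose_pool)
  truth <- list(lactate = M3 %*% t_lac, g6p = M6 %*% t_hex,
                glucose = M6 %*% t_hex)
  with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_replicates)) {
      for (met in names(truth)) {
        x <- as.numeric(truth[[met]]) * pools[[met]]
        if (noise_sd > 0) {
          x <- pmax(x * (1 + stats::rnorm(length(x), 0, noise_sd)), 0)
        }
        row <- as.list(c(rep(NA_real_, 7)))
        names(row) <- paste0("m", 0:6)
        row[seq_along(x)] <- x
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, metabolite = met, n_carbons = length(x) - 1L,
          row, stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag low-yield samples by total-intensity QC
#'
#' A sample whose summed metabolite intensity falls below
#' \code{min_fraction} of the batch median total is flagged for exclusion
#' (exclusions should be logged by the caller, never silent).
#'
#' @param totals named numeric vector of per-sample total intensities.
#' @param min_fraction exclusion threshold as a fraction of the median.
#' @return logical vector, TRUE = excluded.
#' @export
qc_low_yield <- function(totals, min_fraction = 0.5) {
  if (any(totals < 0)) stop_("negative totals")
  totals < min_fraction * stats::median(totals)
}

#' Read / write isotopologue intensity tables as CSV
#'
#' Long-ish format: one row per (sample, replicate, metabolite), columns
#' \code{m0..m<n>} carrying intensities (NA beyond the carbon count).
#'
#' @param df data.frame as produced by \code{\link{simulate_labeling}}.
#' @param path CSV path.
#' @rdname mid_io
#' @export
write_mid_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname mid_io
#' @export
read_mid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_("empty MID table: %s", path)
  df
}
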
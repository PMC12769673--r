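#' Construct a guide count table
#'
#' Couples a guides x samples non-negative integer count matrix with its
#' sample metadata (condition, replicate, timepoint) and, when produced by
#' quantification, per-sample read-accounting statistics satisfying
#' \code{mapped + filtered_low_quality + unmatched = total_reads}.
#'
#' @param counts integer matrix, rownames = guide ids, colnames = samples.
#' @param samples data.frame with columns \code{sample}, \code{condition},
#'   \code{replicate}, \code{timepoint}; rows match count columns.
#' @param stats optional data.frame with columns \code{sample},
#'   \code{total_reads}, \code{mapped_reads}, \code{filtered_low_quality},
#'   \code{unmatched}.
#' @return list of class \code{count_table}.
#' @export
count_table <- function(counts, samples, stats = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_("count matrix needs guide rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_("counts must be non-negative integers")
  }
  need <- c("sample", "condition", "replicate", "timepoint")
  if (!all(need %in% names(samples))) {
    stop_("sample sheet lacks columns: %s",
          paste(setdiff(need, names(samples)), collapse = ", "))
  }
  if (!setequal(samples$sample, colnames(counts))) {
    stop_("sample sheet does not match count columns")
  }
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(stats)) {
    acct <- stats$mapped_reads + stats$filtered_low_quality + stats$unmatched
    if (any(acct != stats$total_reads)) {
      stop_("read accounting violated: mapped + filtered + unmatched != total")
    }
  }
  structure(list(counts = counts, samples = samples, stats = stats),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d guides x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("column sums:", paste(format(colSums(x$counts), big.mark = ","),
                            collapse = " "), "\n")
  invisible(x)
}

#' Library coverage statistics
#'
#' Per-sample and pooled mean reads per guide, fraction of guides with zero
#' reads, and the Gini coefficient of the count distribution (0 = perfectly
#' uniform representation).
#'
#' @param tab a \code{count_table} (or bare count matrix).
#' @return list with \code{per_sample} data.frame
#'   (\code{sample}, \code{mean_reads_per_guide}, \code{fraction_zero_guides},
#'   \code{gini}) and \code{pooled} equivalents over summed counts.
#' @export
coverage_stats <- function(tab) {
  counts <- if (inherits(tab, "count_table")) tab$counts else as.matrix(tab)
  if (ncol(counts) < 1) stop_("coverage_stats: empty count table")
  per <- data.frame(
    sample = colnames(counts),
    mean_reads_per_guide = colMeans(counts),
    fraction_zero_guides = colMeans(counts == 0),
    gini = apply(counts, 2, gini_coef),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pooled <- rowSums(counts)
  list(per_sample = per,
       pooled = list(mean_reads_per_guide = mean(pooled),
                     fraction_zero_guides = mean(pooled == 0),
                     gini = gini_coef(pooled)))
}

gini_coef <- function(x) {
  if (any(x < 0)) stop_("gini undefined for negative counts")
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n == 0 || sum(x) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Read / write count tables and sample sheets as TSV
#'
#' The counts TSV has \code{guide_id} as the first column and one column per
#' sample; the sample sheet carries sample, condition, replicate, timepoint.
#'
#' @param tab a \code{count_table}.
#' @param counts_path,samples_path,stats_path file paths; \code{stats_path}
#'   optional.
#' @rdname counts_io
#' @export
write_counts_tsv <- function(tab, counts_path, samples_path = NULL,
                             stats_path = NULL) {
  df <- data.frame(guide_id = rownames(tab$counts), tab$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_(df, counts_path)
  if (!is.null(samples_path)) write_tsv_(tab$samples, samples_path)
  if (!is.null(stats_path) && !is.null(tab$stats)) write_tsv_(tab$stats, stats_path)
  invisible(counts_path)
}

#' @rdname counts_io
#' @export
read_counts_tsv <- function(counts_path, samples_path, stats_path = NULL) {
  df <- read_tsv_(counts_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$guide_id
  storage.mode(counts) <- "integer"
  samples <- read_tsv_(samples_path)
  stats <- if (!is.null(stats_path)) read_tsv_(stats_path) else NULL
  count_table(counts, samples, stats)
}
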
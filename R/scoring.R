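#' Normalize guide counts to relative abundances
#'
#' Default scheme: per-sample total-count normalization with a pseudocount,
#' \code{(count + pseudocount) / sum(count + pseudocount)}, so columns sum
#' to 1. A median-of-ratios alternative (DESeq-style size factors over the
#' geometric-mean reference guide profile) is available for screens with
#' strong compositional shifts.
#'
#' @param tab a \code{count_table} or bare count matrix.
#' @param pseudocount added to every count before normalization; keeps
#'   fold-changes finite for zero counts.
#' @param method \code{"total"} or \code{"median-ratio"}.
#' @return numeric matrix of relative abundances (guides x samples).
#' @export
normalize_counts <- function(tab, pseudocount = 0.5,
                             method = c("total", "median-ratio")) {
  method <- match.arg(method)
  counts <- if (inherits(tab, "count_table")) tab$counts else as.matrix(tab)
  depth <- colSums(counts)
  if (any(depth == 0)) {
    stop_("zero-depth sample(s): %s",
          paste(colnames(counts)[depth == 0], collapse = ", "))
  }
  x <- counts + pseudocount
  if (method == "total") {
    sweep(x, 2, colSums(x), "/")
  } else {
    logx <- log(x)
    ref <- exp(rowMeans(logx))
    sf <- apply(x, 2, function(col) stats::median(col / ref))
    norm <- sweep(x, 2, sf, "/")
    norm / mean(colSums(norm))
  }
}

#' Per-guide log2 fold-changes versus the T0 baseline
#'
#' For every harvested sample, computes \code{log2(abundance / abundance_T0)}
#' per guide, pairing each treated replicate with the baseline sample of the
#' same replicate (falling back to a single shared baseline when only one T0
#' sample exists). Cross-condition comparison happens later, at the Z level.
#'
#' @param abundances normalized abundance matrix from
#'   \code{\link{normalize_counts}}.
#' @param samples sample sheet (sample, condition, replicate, timepoint).
#' @param baseline_timepoint label of the baseline timepoint.
#' @return data.frame with columns \code{guide_id}, \code{condition},
#'   \code{replicate}, \code{lfc}.
#' @export
guide_lfc <- function(abundances, samples, baseline_timepoint = "T0") {
  base <- samples[samples$timepoint == baseline_timepoint, , drop = FALSE]
  if (nrow(base) == 0) stop_("no baseline samples at timepoint '%s'",
                             baseline_timepoint)
  treated <- samples[samples$timepoint != baseline_timepoint, , drop = FALSE]
  out <- vector("list", nrow(treated))
  for (i in seq_len(nrow(treated))) {
    b <- base$sample[base$replicate == treated$replicate[i]]
    if (length(b) == 0) {
      if (nrow(base) == 1) b <- base$sample else
        stop_("no baseline for replicate %s", treated$replicate[i])
    }
    lfc <- log2(abundances[, treated$sample[i]] / abundances[, b[1]])
    out[[i]] <- data.frame(guide_id = rownames(abundances),
                           condition = treated$condition[i],
                           replicate = treated$replicate[i],
                           lfc = lfc, stringsAsFactors = FALSE,
                           row.names = NULL)
  }
  do.call(rbind, out)
}

#' Gene-level mean log2 fold-change per condition
#'
#' Aggregates guide log2 fold-changes into gene scores by the nested mean:
#' each guide is averaged over replicates, then the gene over its guides.
#' Control guides are excluded from gene scores; their per-condition mean is
#' kept as a diagnostic attribute \code{"control_mean"}.
#'
#' @param lfc data.frame from \code{\link{guide_lfc}}.
#' @param lib a \code{guide_library}.
#' @return genes x conditions matrix of mean log2 fold-changes.
#' @export
gene_score <- function(lfc, lib) {
  validate_library(lib)
  gene_of <- stats::setNames(lib$gene, lib$guide_id)
  if (any(!lfc$guide_id %in% lib$guide_id)) {
    stop_("lfc table names guides absent from library")
  }
  lfc$gene <- gene_of[lfc$guide_id]
  conds <- unique(lfc$condition)
  # guide-level replicate mean, then gene-level guide mean
  gm <- stats::aggregate(lfc ~ guide_id + gene + condition, data = lfc, FUN = mean)
  target <- gm[gm$gene != "CONTROL", , drop = FALSE]
  genes <- sort(unique(target$gene))
  score <- matrix(NA_real_, nrow = length(genes), ncol = length(conds),
                  dimnames = list(genes, conds))
  for (cond in conds) {
    sub <- target[target$condition == cond, , drop = FALSE]
    agg <- tapply(sub$lfc, sub$gene, mean)
    score[names(agg), cond] <- agg
  }
  ctrl <- gm[gm$gene == "CONTROL", , drop = FALSE]
  if (nrow(ctrl)) {
    attr(score, "control_mean") <- tapply(ctrl$lfc, ctrl$condition, mean)[conds]
  }
  score
}

#' Z-score gene scores within each condition
#'
#' Standardizes gene-level scores per condition using the mean and the
#' population standard deviation over gene-targeting genes, so each column
#' has mean 0 and SD 1 exactly.
#'
#' @param score genes x conditions matrix from \code{\link{gene_score}}.
#' @return matrix of the same shape with standardized columns.
#' @export
zscore_genes <- function(score) {
  if (nrow(score) < 2) stop_("z-scoring needs at least 2 genes")
  apply(score, 2, function(x) {
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))
    if (sdev == 0) stop_("degenerate screen: zero SD of gene scores")
    (x - mu) / sdev
  })
}

#' Z-score difference between two conditions (sigma-plot quantity)
#'
#' \code{delta_z(g) = z_a(g) - z_b(g)}. For suppressor contrasts put the drug
#' arm first and the reference second, so suppressors (knockouts enriched
#' under drug) come out positive and synthetic-sick genes negative.
#'
#' @param z genes x conditions Z matrix.
#' @param condition_a,condition_b condition labels.
#' @return named numeric vector of per-gene Z differences.
#' @export
sigma_diff <- function(z, condition_a, condition_b) {
  for (cond in c(condition_a, condition_b)) {
    if (!cond %in% colnames(z)) stop_("condition '%s' not scored", cond)
  }
  stats::setNames(z[, condition_a] - z[, condition_b], rownames(z))
}

#' Call suppressor and synthetic-sick hits at a fixed Z-difference threshold
#'
#' Suppressors are genes with \code{delta_z >= threshold} (inclusive),
#' synthetic-sick genes those with \code{delta_z <= -threshold}. Output is
#' sorted by \code{|delta_z|} descending, ties broken by gene symbol.
#'
#' @param delta_z named per-gene Z-difference vector from
#'   \code{\link{sigma_diff}}.
#' @param threshold positive cut-off (default 3).
#' @param direction \code{"both"}, \code{"suppressor"} or
#'   \code{"synthetic_sick"}.
#' @param contrast optional contrast label stored with the calls.
#' @return data.frame with columns \code{gene}, \code{direction},
#'   \code{delta_z}, \code{threshold}, \code{contrast}.
#' @export
call_hits <- function(delta_z, threshold = 3,
                      direction = c("both", "suppressor", "synthetic_sick"),
                      contrast = NA_character_) {
  direction <- match.arg(direction)
  if (threshold <= 0) stop_("threshold must be > 0")
  up <- delta_z >= threshold
  dn <- delta_z <= -threshold
  sel <- switch(direction, both = up | dn, suppressor = up, synthetic_sick = dn)
  out <- data.frame(
    gene = names(delta_z)[sel],
    direction = ifelse(up[sel], "suppressor", "synthetic_sick"),
    delta_z = unname(delta_z[sel]),
    threshold = rep(threshold, sum(sel)),
    contrast = rep(contrast, sum(sel)),
    stringsAsFactors = FALSE
  )
  out[order(-abs(out$delta_z), out$gene), , drop = FALSE]
}

#' Score a pooled screen end to end
#'
#' The package's central fit: normalizes counts, computes per-guide log2
#' fold-changes against T0, aggregates to gene scores (guide and replicate
#' means first, Z-transform after — the default order; set
#' \code{z_before_average = TRUE} to z-score guide-level fold-changes first
#' and average z per gene afterwards), standardizes per condition, and forms
#' Z-differences for the requested contrasts.
#'
#' @param tab a \code{count_table}.
#' @param lib a \code{guide_library}.
#' @param contrasts list of 2-vectors \code{c(drug, reference)}; default
#'   contrasts every non-baseline condition against the first condition
#'   encountered that looks like a solvent reference ("ETOH" if present).
#' @param pseudocount,normalization passed to \code{\link{normalize_counts}}.
#' @param z_before_average aggregation-order switch (see Details).
#' @param baseline_timepoint baseline label, default "T0".
#' @return object of class \code{screen_fit}: list with \code{lfc} (guide
#'   level), \code{gene_lfc} (genes x conditions), \code{z}, \code{delta_z}
#'   (genes x contrasts), \code{contrasts}, \code{params}.
#' @export
score_screen <- function(tab, lib, contrasts = NULL, pseudocount = 0.5,
                         normalization = "total", z_before_average = FALSE,
                         baseline_timepoint = "T0") {
  validate_library(lib)
  ab <- normalize_counts(tab, pseudocount, normalization)
  lfc <- guide_lfc(ab, tab$samples, baseline_timepoint)
  if (z_before_average) {
    gene_of <- stats::setNames(lib$gene, lib$guide_id)
    gm <- stats::aggregate(lfc ~ guide_id + condition, data = lfc, FUN = mean)
    gm$gene <- gene_of[gm$guide_id]
    tg <- gm[gm$gene != "CONTROL", , drop = FALSE]
    conds <- unique(tg$condition)
    genes <- sort(unique(tg$gene))
    score <- matrix(NA_real_, length(genes), length(conds),
                    dimnames = list(genes, conds))
    for (cond in conds) {
      sub <- tg[tg$condition == cond, , drop = FALSE]
      mu <- mean(sub$lfc); sdev <- sqrt(mean((sub$lfc - mu)^2))
      if (sdev == 0) stop_("degenerate screen: zero SD of guide fold-changes")
      sub$zg <- (sub$lfc - mu) / sdev
      agg <- tapply(sub$zg, sub$gene, mean)
      score[names(agg), cond] <- agg
    }
    gene_lfc <- score
  } else {
    gene_lfc <- gene_score(lfc, lib)
  }
  z <- zscore_genes(gene_lfc)
  if (is.null(contrasts)) {
    conds <- unique(lfc$condition)
    ref <- if ("ETOH" %in% conds) "ETOH" else conds[1]
    contrasts <- lapply(setdiff(conds, ref), function(a) c(a, ref))
  }
  dz <- sapply(contrasts, function(ct) sigma_diff(z, ct[1], ct[2]))
  colnames(dz) <- vapply(contrasts, function(ct) paste0(ct[1], "_vs_", ct[2]),
                         character(1))
  structure(list(
    lfc = lfc, gene_lfc = gene_lfc, z = z, delta_z = dz,
    contrasts = contrasts,
    params = list(pseudocount = pseudocount, normalization = normalization,
                  z_before_average = z_before_average,
                  baseline_timepoint = baseline_timepoint)
  ), class = "screen_fit")
}

#' @export
print.screen_fit <- function(x, ...) {
  cat(sprintf("screen_fit: %d genes, %d conditions, %d contrast(s)\n",
              nrow(x$z), ncol(x$z), ncol(x$delta_z)))
  cat("conditions:", paste(colnames(x$z), collapse = ", "), "\n")
  cat("contrasts: ", paste(colnames(x$delta_z), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.screen_fit <- function(object, threshold = 3, ...) {
  cat(sprintf("Pooled screen fit over %d genes\n", nrow(object$z)))
  for (ct in colnames(object$delta_z)) {
    hits <- call_hits(object$delta_z[, ct], threshold, contrast = ct)
    cat(sprintf("\nContrast %s: %d suppressor(s), %d synthetic sick at |dZ| >= %g\n",
                ct, sum(hits$direction == "suppressor"),
                sum(hits$direction == "synthetic_sick"), threshold))
    if (nrow(hits)) {
      print(utils::head(hits[, c("gene", "direction", "delta_z")], 10),
            row.names = FALSE)
    }
  }
  invisible(object)
}

#' @export
coef.screen_fit <- function(object, ...) object$z

#' Sigma plot: ranked per-gene Z differences for one contrast
#'
#' @param x a \code{screen_fit}.
#' @param contrast contrast column name (default: first).
#' @param threshold hit threshold drawn as horizontal guides.
#' @param ... passed to \code{plot}.
#' @export
plot.screen_fit <- function(x, contrast = colnames(x$delta_z)[1],
                            threshold = 3, ...) {
  dz <- sort(x$delta_z[, contrast])
  cols <- ifelse(dz >= threshold, "darkorange",
                 ifelse(dz <= -threshold, "firebrick", "grey50"))
  graphics::plot(seq_along(dz), dz, pch = 16, cex = 0.4, col = cols,
                 xlab = "gene rank", ylab = expression(Delta * Z),
                 main = paste("Sigma plot:", contrast), ...)
  graphics::abline(h = c(-threshold, threshold), lty = 2, col = "grey40")
  invisible(x)
}

#' Export a ranked sigma table for one contrast
#'
#' One row per gene: rank (1 = largest Z difference), gene, the two
#' condition Z-scores, their difference, and the hit flag at the given
#' threshold. Ordering is deterministic (delta_z descending, ties by gene).
#'
#' @param fit a \code{screen_fit}.
#' @param contrast contrast column name.
#' @param path output TSV path.
#' @param threshold hit threshold recorded in the \code{hit} column.
#' @return the exported data.frame, invisibly.
#' @export
export_sigma_table <- function(fit, contrast, path, threshold = 3) {
  if (!contrast %in% colnames(fit$delta_z)) {
    stop_("contrast '%s' not computed", contrast)
  }
  ct <- fit$contrasts[[match(contrast, colnames(fit$delta_z))]]
  dz <- fit$delta_z[, contrast]
  ord <- order(-dz, names(dz))
  df <- data.frame(
    rank = seq_along(dz),
    gene = names(dz)[ord],
    z_a = unname(fit$z[ord, ct[1]]),
    z_b = unname(fit$z[ord, ct[2]]),
    delta_z = unname(dz[ord]),
    hit = abs(unname(dz[ord])) >= threshold,
    stringsAsFactors = FALSE
  )
  write_tsv_(df, path)
  invisible(df)
}
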
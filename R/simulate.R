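#' Describe the design of a pooled fitness screen
#'
#' Collects the experimental parameters of a drug-selection knockout screen:
#' treatment arms with a solvent reference, replicate count, duration,
#' passaging interval, bottleneck size, sequencing depth, the untreated
#' doubling time and per-condition growth inhibition. Defaults reproduce a
#' 15-day screen passaged every 72 h at 4e7 cells with three replicates,
#' four arms (solvent EtOH reference, ACT, CAP, ACT+CAP) and roughly 40%
#' growth inhibition in each drug arm so that arms stay comparable.
#'
#' @param conditions character vector of condition labels; the first is not
#'   required to be the reference.
#' @param reference reference (solvent control) condition label.
#' @param n_replicates replicates per condition.
#' @param duration_days total treatment duration in days.
#' @param passage_interval_h hours between passages; must divide the duration.
#' @param bottleneck_cells cells re-seeded at each passage.
#' @param reads_per_sample sequencing reads per sample; \code{NULL} means
#'   150 reads per guide (about 150x coverage), resolved when counts are drawn.
#' @param untreated_doubling_time_h doubling time without drug, hours.
#' @param growth_inhibition named fractional growth-rate reduction per
#'   condition in [0, 1); unnamed conditions default to 0, and the reference
#'   is always 0.
#' @return list of class \code{screen_design}.
#' @export
screen_design <- function(conditions = c("ETOH", "ACT", "CAP", "ACTCAP"),
                          reference = "ETOH",
                          n_replicates = 3L,
                          duration_days = 15,
                          passage_interval_h = 72,
                          bottleneck_cells = 4e7,
                          reads_per_sample = NULL,
                          untreated_doubling_time_h = 24,
                          growth_inhibition = NULL) {
  if (!reference %in% conditions) stop_("reference condition '%s' absent", reference)
  n_pass <- duration_days * 24 / passage_interval_h
  if (abs(n_pass - round(n_pass)) > 1e-9) {
    stop_("duration (%g days) is not a whole number of %g-h passages",
          duration_days, passage_interval_h)
  }
  if (is.null(growth_inhibition)) {
    growth_inhibition <- stats::setNames(
      ifelse(conditions == reference, 0, 0.40), conditions)
  }
  gi <- stats::setNames(rep(0, length(conditions)), conditions)
  gi[names(growth_inhibition)] <- growth_inhibition
  gi[reference] <- 0
  if (any(gi < 0 | gi >= 1)) stop_("growth_inhibition must lie in [0, 1)")
  structure(list(
    conditions = conditions, reference = reference,
    n_replicates = as.integer(n_replicates),
    duration_days = duration_days,
    passage_interval_h = passage_interval_h,
    n_passages = as.integer(round(n_pass)),
    bottleneck_cells = bottleneck_cells,
    reads_per_sample = reads_per_sample,
    untreated_doubling_time_h = untreated_doubling_time_h,
    growth_inhibition = gi,
    baseline_timepoint = "T0"
  ), class = "screen_design")
}

#' Doublings per passage for one condition
#'
#' Under the exponential growth model a condition accrues
#' \code{passage_interval_h / untreated_doubling_time_h * (1 - inhibition)}
#' population doublings per passage.
#'
#' @param design a \code{screen_design}.
#' @param condition condition label.
#' @return doublings per passage (numeric).
#' @export
doublings_per_passage <- function(design, condition) {
  if (!condition %in% design$conditions) stop_("unknown condition '%s'", condition)
  design$passage_interval_h / design$untreated_doubling_time_h *
    (1 - design$growth_inhibition[[condition]])
}

#' Assign ground-truth fitness effects to a simulated screen
#'
#' Labels genes as suppressors (knockout enriched under drug, selection
#' coefficient s > 0), synthetic sick (depleted, s < 0) or neutral (s = 0),
#' per condition. A shared synthetic-sick set — emulating pathway knockouts
#' (e.g. glycolysis) that are sick in every drug arm of a mitochondrial
#' screen — receives the sick coefficient in all non-reference conditions.
#' The reference arm is all-neutral, as are control guides. Each guide gets
#' an efficacy in [0, 1], the fraction of transduced cells in which the
#' knockout is effective; the realized per-guide coefficient is
#' \code{efficacy * s}.
#'
#' @param lib a \code{guide_library}.
#' @param design a \code{screen_design}.
#' @param class_spec named list, one entry per (non-reference) condition, each
#'   a list with \code{n_suppressors}, \code{n_sick}, \code{s_suppressor},
#'   \code{s_sick}. Conditions absent from the list are all-neutral.
#' @param shared_sick_genes number of genes sick in every non-reference arm.
#' @param s_shared_sick selection coefficient for the shared sick set.
#' @param efficacy_shape Beta(a, b) parameters for guide efficacy; the
#'   default Beta(8, 2) gives mean efficacy 0.8.
#' @param seed integer seed.
#' @return list of class \code{fitness_truth} with elements \code{s}
#'   (genes x conditions matrix of selection coefficients), \code{gene_class}
#'   (genes x conditions character matrix), \code{guide_efficacy} (named
#'   vector over guide ids; controls fixed at efficacy with s = 0).
#' @export
assign_fitness <- function(lib, design, class_spec = list(),
                           shared_sick_genes = 0L, s_shared_sick = -0.4,
                           efficacy_shape = c(8, 2), seed = 1L) {
  validate_library(lib)
  genes <- unique(lib$gene[!lib$is_control])
  conds <- design$conditions
  s <- matrix(0, nrow = length(genes), ncol = length(conds),
              dimnames = list(genes, conds))
  cls <- matrix("neutral", nrow = length(genes), ncol = length(conds),
                dimnames = list(genes, conds))
  bad <- setdiff(names(class_spec), conds)
  if (length(bad)) stop_("class_spec names unknown conditions: %s",
                         paste(bad, collapse = ", "))
  if (design$reference %in% names(class_spec)) {
    stop_("reference condition must stay neutral")
  }
  with_seed(seed, {
    shared <- character(0)
    if (shared_sick_genes > 0) {
      if (shared_sick_genes > length(genes)) stop_("shared sick set exceeds gene count")
      shared <- sample(genes, shared_sick_genes)
      for (cond in setdiff(conds, design$reference)) {
        s[shared, cond] <- s_shared_sick
        cls[shared, cond] <- "synthetic_sick"
      }
    }
    for (cond in names(class_spec)) {
      sp <- class_spec[[cond]]
      n_sup <- sp$n_suppressors %||% 0L
      n_sick <- sp$n_sick %||% 0L
      pool <- setdiff(genes, shared)
      if (n_sup + n_sick > length(pool)) {
        stop_("condition %s requests %d labelled genes but only %d available",
              cond, n_sup + n_sick, length(pool))
      }
      pick <- sample(pool, n_sup + n_sick)
      if (n_sup > 0) {
        sup <- pick[seq_len(n_sup)]
        s[sup, cond] <- sp$s_suppressor %||% 0.4
        cls[sup, cond] <- "suppressor"
      }
      if (n_sick > 0) {
        sick <- pick[n_sup + seq_len(n_sick)]
        s[sick, cond] <- sp$s_sick %||% -0.4
        cls[sick, cond] <- "synthetic_sick"
      }
    }
    eff <- stats::setNames(
      stats::rbeta(nrow(lib), efficacy_shape[1], efficacy_shape[2]),
      lib$guide_id)
  })
  structure(list(s = s, gene_class = cls, guide_efficacy = eff, seed = seed),
            class = "fitness_truth")
}

# Realized per-guide, per-condition selection coefficient matrix.
guide_selection <- function(lib, truth, design) {
  s_g <- matrix(0, nrow = nrow(lib), ncol = length(design$conditions),
                dimnames = list(lib$guide_id, design$conditions))
  idx <- !lib$is_control
  s_g[idx, ] <- truth$s[lib$gene[idx], , drop = FALSE] *
    truth$guide_efficacy[lib$guide_id[idx]]
  s_g
}

#' Simulate guide abundance trajectories across screen passages
#'
#' Deterministic exponential competition with bottleneck renormalization:
#' between passages, guide g in condition c multiplies by
#' \code{2^(D_c * (1 + s_eff(g, c)))} where \code{D_c} is the condition's
#' doublings per passage and \code{s_eff} the efficacy-weighted selection
#' coefficient; each bottleneck renormalizes relative abundances to sum to 1.
#' Initial abundances are lognormal (library skew, sigma in log2 units).
#' Optional per-passage multiplicative lognormal jitter models biological
#' noise in growth; optional multinomial bottleneck sampling at the design's
#' bottleneck size models genetic drift. Both are off by default.
#'
#' @param lib a \code{guide_library}.
#' @param truth a \code{fitness_truth}.
#' @param design a \code{screen_design}.
#' @param sigma_log2_initial lognormal skew (SD in log2 units) of the initial
#'   plasmid-pool abundances.
#' @param growth_jitter_sd per-passage lognormal growth noise SD in log2
#'   units (0 = deterministic growth).
#' @param bottleneck_sampling if \code{TRUE}, resample abundances
#'   multinomially at \code{bottleneck_cells} each passage (drift).
#' @param seed integer seed.
#' @return list of class \code{abundance_trajectory}: \code{initial}
#'   (abundance vector over guides, the T0 composition), \code{final}
#'   (guides x (condition x replicate) abundance matrix at harvest),
#'   \code{cumulative_doublings} (conditions x passages matrix of cumulative
#'   population doublings), plus the design.
#' @export
simulate_passaging <- function(lib, truth, design,
                               sigma_log2_initial = 0.5,
                               growth_jitter_sd = 0,
                               bottleneck_sampling = FALSE,
                               seed = 1L) {
  validate_library(lib)
  n_g <- nrow(lib)
  s_g <- guide_selection(lib, truth, design)
  with_seed(seed, {
    a0 <- stats::rlnorm(n_g, meanlog = 0, sdlog = sigma_log2_initial * log(2))
    a0 <- a0 / sum(a0)
    names(a0) <- lib$guide_id

    cols <- as.vector(outer(seq_len(design$n_replicates), design$conditions,
                            function(r, c) paste0(c, "_R", r)))
    final <- matrix(NA_real_, nrow = n_g, ncol = length(cols),
                    dimnames = list(lib$guide_id, cols))
    cum_d <- matrix(0, nrow = length(design$conditions),
                    ncol = design$n_passages,
                    dimnames = list(design$conditions, NULL))
    for (cond in design$conditions) {
      D <- doublings_per_passage(design, cond)
      growth <- 2^(D * (1 + s_g[, cond]))
      for (r in seq_len(design$n_replicates)) {
        a <- a0
        cd <- 0
        for (p in seq_len(design$n_passages)) {
          g <- growth
          if (growth_jitter_sd > 0) {
            g <- g * 2^stats::rnorm(n_g, 0, growth_jitter_sd)
          }
          grown <- a * g
          pop_factor <- sum(grown)
          cd <- cd + log2(pop_factor)
          a <- grown / pop_factor
          if (bottleneck_sampling) {
            counts <- stats::rmultinom(1, size = design$bottleneck_cells, prob = a)[, 1]
            a <- counts / sum(counts)
          }
          # record replicate 1's cumulative population doublings per passage
          if (r == 1L) cum_d[cond, p] <- cd
        }
        final[, paste0(cond, "_R", r)] <- a
      }
    }
  })
  structure(list(initial = a0, final = final,
                 cumulative_doublings = cum_d, design = design),
            class = "abundance_trajectory")
}

#' Draw sequencing counts from an abundance trajectory
#'
#' Each harvest sample is a multinomial draw of \code{reads_per_sample} reads
#' with probabilities equal to that replicate's final abundances; T0 baseline
#' samples (one per replicate) draw from the pre-treatment composition.
#' Optional Dirichlet overdispersion perturbs the probabilities before each
#' draw to model library-prep variability.
#'
#' @param traj an \code{abundance_trajectory}.
#' @param design a \code{screen_design}; \code{reads_per_sample = NULL}
#'   resolves to 150 reads per guide.
#' @param overdispersion Dirichlet overdispersion: probabilities are drawn
#'   from Dirichlet(abundance / overdispersion) when > 0; 0 disables.
#' @param seed integer seed.
#' @return a \code{count_table} (see \code{\link{count_table}}) whose columns
#'   are T0 samples followed by condition x replicate harvest samples.
#' @export
sample_counts <- function(traj, design = traj$design, overdispersion = 0,
                          seed = 1L) {
  reads <- design$reads_per_sample %||% (150L * length(traj$initial))
  if (reads < 1) stop_("reads_per_sample must be >= 1")
  draw <- function(p) {
    if (overdispersion > 0) {
      g <- stats::rgamma(length(p), shape = p / overdispersion)
      p <- if (sum(g) > 0) g / sum(g) else p
    }
    stats::rmultinom(1, size = reads, prob = p)[, 1]
  }
  with_seed(seed, {
    t0 <- sapply(seq_len(design$n_replicates), function(r) draw(traj$initial))
    colnames(t0) <- paste0("T0_R", seq_len(design$n_replicates))
    harvest <- apply(traj$final, 2, draw)
    counts <- cbind(t0, harvest)
  })
  rownames(counts) <- names(traj$initial)
  samples <- rbind(
    data.frame(sample = colnames(t0), condition = "T0",
               replicate = seq_len(design$n_replicates), timepoint = "T0",
               stringsAsFactors = FALSE),
    data.frame(sample = colnames(traj$final),
               condition = sub("_R[0-9]+$", "", colnames(traj$final)),
               replicate = as.integer(sub("^.*_R", "", colnames(traj$final))),
               timepoint = "D15", stringsAsFactors = FALSE)
  )
  count_table(counts, samples)
}

#' Emit synthetic FASTQ reads for one sample
#'
#' Writes one read per counted guide occurrence: vector prefix +
#' protospacer + vector suffix, with independent per-base substitution
#' errors at \code{error_rate}. A fraction of reads is assigned a low
#' per-base Phred score (below the usual mean-Phred 20 filter), the rest a
#' high score; qualities are Phred+33 encoded. Read order is shuffled.
#'
#' @param counts named integer vector (names = guide ids) of read counts.
#' @param lib a \code{guide_library} covering all counted guides.
#' @param path output FASTQ path (".gz" suffix writes gzip).
#' @param prefix,suffix vector context flanking the protospacer in each read.
#' @param phred_high,phred_low per-base quality of normal / low-quality reads.
#' @param fraction_low fraction of reads assigned \code{phred_low}.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return \code{path}, invisibly.
#' @export
emit_fastq <- function(counts, lib, path,
                       prefix = "ACCG", suffix = "GTTTAAGAGCTAAGCTGG",
                       phred_high = 37L, phred_low = 12L,
                       fraction_low = 0, error_rate = 0, seed = 1L) {
  validate_library(lib)
  counts <- counts[counts > 0]
  if (length(counts) && !all(names(counts) %in% lib$guide_id)) {
    stop_("counts name guides absent from library")
  }
  if (phred_high < 2 || phred_high > 41 || phred_low < 2 || phred_low > 41) {
    stop_("Phred values must lie in [2, 41]")
  }
  spacer <- stats::setNames(lib$protospacer, lib$guide_id)
  n_reads <- sum(counts)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (n_reads == 0) return(invisible(path))
  with_seed(seed, {
    guide_of <- sample(rep(names(counts), times = counts))
    seqs <- paste0(prefix, spacer[guide_of], suffix)
    read_len <- nchar(seqs[1])
    if (error_rate > 0) {
      seqs <- mutate_bases(seqs, error_rate)
    }
    low <- stats::runif(n_reads) < fraction_low
    qual_chr <- function(phred) strrep(intToUtf8(phred + 33L), read_len)
    quals <- ifelse(low, qual_chr(phred_low), qual_chr(phred_high))
  })
  ids <- sprintf("@read_%06d %s", seq_len(n_reads), guide_of)
  writeLines(paste(ids, seqs, "+", quals, sep = "\n"), con)
  invisible(path)
}

# Independent per-base substitutions to a uniformly chosen different base.
mutate_bases <- function(seqs, rate) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  hit <- which(matrix(stats::runif(length(mat)) < rate, nrow = nrow(mat)))
  if (length(hit)) {
    cur <- mat[hit]
    alt <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
    mat[hit] <- alt
  }
  apply(mat, 1, paste, collapse = "")
}
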
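# Shared fixtures and independent oracles used across test files.

# Small screen design used by most simulator tests: 2 arms, 3 replicates,
# 15 days / 72 h passages, 40% inhibition in the drug arm.
small_design <- function(conditions = c("ETOH", "ACT"), n_replicates = 3L,
                         reads_per_sample = NULL, ...) {
  screen_design(conditions = conditions, reference = "ETOH",
                n_replicates = n_replicates,
                reads_per_sample = reads_per_sample, ...)
}

# All-neutral ground truth for a library.
neutral_truth <- function(lib, design, seed = 1L) {
  assign_fitness(lib, design, class_spec = list(), seed = seed)
}

# One complete simulated screen (counts + library + truth), with optional
# planted suppressors in the ACT arm.
simulate_screen <- function(n_genes = 200L, guides_per_gene = 4L,
                            n_controls = 20L, n_suppressors = 0L,
                            s_suppressor = 0.4, design = small_design(),
                            seed = 1L) {
  lib <- build_library(n_genes, guides_per_gene, n_controls,
                       seed = child_seed(seed, "lib"))
  spec <- if (n_suppressors > 0) {
    list(ACT = list(n_suppressors = n_suppressors, n_sick = 0L,
                    s_suppressor = s_suppressor, s_sick = 0))
  } else list()
  truth <- assign_fitness(lib, design, spec, seed = child_seed(seed, "truth"))
  traj <- simulate_passaging(lib, truth, design,
                             seed = child_seed(seed, "traj"))
  tab <- sample_counts(traj, design, seed = child_seed(seed, "counts"))
  list(lib = lib, truth = truth, traj = traj, tab = tab)
}

# Independent hypergeometric right-tail oracle: direct enumeration of the
# PMF from binomial coefficients, summed over k >= a.
hyper_tail_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c
  ks <- max(0, K - n):min(m, K)
  pmf <- choose(m, ks) * choose(n, K - ks) / choose(m + n, K)
  sum(pmf[ks >= a])
}

# Independent correction-matrix oracle: exhaustive enumeration over all 2^n
# per-carbon isotope assignments for a molecule with j tracer labels.
correction_column_oracle <- function(n, j, p13, purity) {
  p_is13 <- c(rep(purity, j), rep(p13, n - j))
  col <- numeric(n + 1)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    pr <- prod(ifelse(bits == 1, p_is13, 1 - p_is13))
    mass <- sum(bits)
    col[mass + 1] <- col[mass + 1] + pr
  }
  col
}

# Rank-based AUROC of scores for positives vs negatives.
auroc <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Phred+33 quality string of length n at a constant score.
qual_string <- function(phred, n) strrep(intToUtf8(phred + 33L), n)
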
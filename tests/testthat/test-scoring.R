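test_that("total-count normalization follows the pseudocount arithmetic", {
  m <- matrix(c(10L, 10L), ncol = 1, dimnames = list(c("g1", "g2"), "s"))
  expect_equal(unname(normalize_counts(m, pseudocount = 0)[, 1]), c(0.5, 0.5))
  m2 <- matrix(c(0L, 100L), ncol = 1, dimnames = list(c("g1", "g2"), "s"))
  expect_equal(unname(normalize_counts(m2, pseudocount = 0.5)[, 1]),
               c(0.5 / 101, 100.5 / 101))
  # scale invariance: doubling all counts leaves abundances unchanged
  m3 <- matrix(rpois(20, 50), ncol = 2,
               dimnames = list(paste0("g", 1:10), c("a", "b")))
  expect_equal(normalize_counts(m3, 0), normalize_counts(2L * m3, 0))
  expect_true(all(abs(colSums(normalize_counts(m3)) - 1) < 1e-12))
})

test_that("zero-depth samples are rejected by name", {
  m <- matrix(c(5L, 5L, 0L, 0L), ncol = 2,
              dimnames = list(c("g1", "g2"), c("ok", "empty")))
  expect_error(normalize_counts(m), "empty")
})

test_that("guide log2 fold-changes compare each replicate to its T0", {
  ab <- matrix(c(0.5, 0.5, 0.5, 0.5, 0.25, 0.75), ncol = 3,
               dimnames = list(c("g1", "g2"), c("T0_R1", "ACT_R1", "ACT_R2")))
  sam <- data.frame(sample = colnames(ab), condition = c("T0", "ACT", "ACT"),
                    replicate = c(1, 1, 2), timepoint = c("T0", "D15", "D15"))
  lfc <- guide_lfc(ab, sam)
  expect_equal(lfc$lfc[lfc$replicate == 1], c(0, 0))          # unchanged
  expect_equal(lfc$lfc[lfc$replicate == 2], c(-1, log2(1.5))) # halves / rises
  sam_nobase <- sam[sam$timepoint != "T0", ]
  expect_error(guide_lfc(ab[, -1], sam_nobase), "baseline")
})

test_that("simulator fold-changes match the passaging closed form", {
  # s_eff = +0.5 over 3 drug-arm doublings: lfc - median(neutral lfc) = 1.5
  lib <- build_library(10, 1, 0, seed = 1)
  des <- screen_design(conditions = c("ETOH", "ACT"), reference = "ETOH",
                       n_replicates = 1, duration_days = 3,
                       growth_inhibition = c(ACT = 0))
  truth <- neutral_truth(lib, des)
  truth$s["GENE00001", "ACT"] <- 0.5
  truth$guide_efficacy[] <- 1
  traj <- simulate_passaging(lib, truth, des, seed = 2)
  ab <- cbind(T0_R1 = traj$initial, traj$final)
  sam <- data.frame(sample = colnames(ab),
                    condition = c("T0", "ETOH", "ACT"),
                    replicate = 1, timepoint = c("T0", "D15", "D15"))
  lfc <- guide_lfc(ab, sam)
  act <- lfc[lfc$condition == "ACT", ]
  hit <- act$lfc[act$guide_id == "GENE00001_g1"]
  neutral_med <- median(act$lfc[act$guide_id != "GENE00001_g1"])
  expect_equal(hit - neutral_med, 1.5, tolerance = 1e-9)
})

test_that("gene scores equal the brute-force nested mean", {
  lib <- build_library(6, 3, 2, seed = 5)
  set.seed(7)
  grid <- expand.grid(guide_id = lib$guide_id, condition = c("ACT", "ETOH"),
                      replicate = 1:3, stringsAsFactors = FALSE)
  grid$lfc <- rnorm(nrow(grid))
  score <- gene_score(grid, lib)
  # independent oracle: explicit nested loops
  for (g in rownames(score)) {
    for (cond in colnames(score)) {
      guides <- lib$guide_id[lib$gene == g]
      per_guide <- sapply(guides, function(gu) {
        mean(grid$lfc[grid$guide_id == gu & grid$condition == cond])
      })
      expect_equal(unname(score[g, cond]), mean(per_guide))
    }
  }
  # control guides excluded from gene scores, kept as diagnostic
  expect_false("CONTROL" %in% rownames(score))
  expect_length(attr(score, "control_mean"), 2)
})

test_that("gene score handles the textbook toy cases", {
  lib <- validate_library(data.frame(
    guide_id = paste0("G_g", 1:4), gene = "G",
    protospacer = replicate(4, paste(sample(c("A", "C", "G", "T"), 20,
                                            TRUE), collapse = "")),
    is_control = FALSE, stringsAsFactors = FALSE))
  d1 <- expand.grid(guide_id = lib$guide_id, condition = "ACT",
                    replicate = 1:3, stringsAsFactors = FALSE)
  d1$lfc <- 1
  expect_equal(unname(gene_score(d1, lib)["G", "ACT"]), 1)
  d2 <- data.frame(guide_id = lib$guide_id[1:2], condition = "ACT",
                   replicate = 1, lfc = c(0, 2))
  expect_equal(unname(gene_score(d2, lib)["G", "ACT"]), 1)
})

test_that("z-scoring standardizes with the population SD", {
  m <- matrix(c(-1, 0, 1), ncol = 1,
              dimnames = list(c("a", "b", "c"), "ACT"))
  z <- zscore_genes(m)
  expect_equal(unname(z[, 1]), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(z["c", 1]), 1.2247449, tolerance = 1e-6)
  # normalization identity on arbitrary input
  set.seed(3)
  r <- matrix(rnorm(200), ncol = 2,
              dimnames = list(paste0("g", 1:100), c("A", "B")))
  zr <- zscore_genes(r)
  expect_true(all(abs(colMeans(zr)) < 1e-8))
  expect_true(all(abs(apply(zr, 2, function(x) sqrt(mean(x^2))) - 1) < 1e-8))
  # degenerate screens are refused
  expect_error(zscore_genes(matrix(1, 3, 1,
                                   dimnames = list(letters[1:3], "A"))),
               "zero SD")
})

test_that("sigma differences subtract Z columns with the suppressor sign convention", {
  z <- matrix(c(1, -2, 0.5, 0.5), ncol = 2,
              dimnames = list(c("g1", "g2"), c("ACT", "ETOH")))
  dz <- sigma_diff(z, "ACT", "ETOH")
  expect_equal(unname(dz), c(0.5, -2.5))
  expect_equal(unname(sigma_diff(z, "ACT", "ACT")), c(0, 0))
  expect_error(sigma_diff(z, "ACT", "CAP"), "not scored")
})

test_that("hit calling is inclusive at the threshold and deterministically ordered", {
  dz <- c(a = 2.9, b = 3.0, c = -3.0, d = 0.1, e = 5, f = -5)
  h <- call_hits(dz, threshold = 3)
  expect_setequal(h$gene, c("b", "c", "e", "f"))
  expect_true("b" %in% h$gene)  # delta_z exactly 3.0 is called
  expect_equal(h$gene, c("e", "f", "b", "c"))  # |dz| desc, ties by gene
  expect_equal(h$direction[h$gene == "c"], "synthetic_sick")
  expect_equal(nrow(call_hits(c(x = 1, y = -2), 3)), 0)
  expect_equal(call_hits(dz, 3, direction = "suppressor")$gene, c("e", "b"))
  expect_error(call_hits(dz, threshold = 0), "> 0")
})

test_that("sigma tables export deterministically and round-trip", {
  sim <- simulate_screen(n_genes = 40, n_suppressors = 4, seed = 13)
  fit <- score_screen(sim$tab, sim$lib, contrasts = list(c("ACT", "ETOH")))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  df <- export_sigma_table(fit, "ACT_vs_ETOH", f1)
  export_sigma_table(fit, "ACT_vs_ETOH", f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical re-export
  expect_equal(df$rank[1], 1)
  expect_equal(df$gene[1], names(which.max(fit$delta_z[, 1])))
  back <- read.delim(f1)
  expect_equal(back$delta_z, df$delta_z, tolerance = 1e-10)
  expect_equal(back$gene, df$gene)
  expect_error(export_sigma_table(fit, "CAP_vs_ETOH", f1), "not computed")
})

test_that("permuting gene labels permutes scores identically", {
  sim <- simulate_screen(n_genes = 30, n_suppressors = 3, seed = 21)
  fit <- score_screen(sim$tab, sim$lib, contrasts = list(c("ACT", "ETOH")))
  # relabel genes by a fixed permutation of gene symbols
  genes <- unique(sim$lib$gene[!sim$lib$is_control])
  set.seed(1)
  perm <- stats::setNames(sample(genes), genes)
  lib2 <- sim$lib
  lib2$gene[!lib2$is_control] <- unname(perm[lib2$gene[!lib2$is_control]])
  fit2 <- score_screen(sim$tab, lib2, contrasts = list(c("ACT", "ETOH")))
  expect_equal(fit2$delta_z[unname(perm[genes]), 1],
               stats::setNames(fit$delta_z[genes, 1], unname(perm[genes])))
})

test_that("both aggregation orders give self-consistent standardized scores", {
  sim <- simulate_screen(n_genes = 50, n_suppressors = 5, seed = 31)
  f_avg <- score_screen(sim$tab, sim$lib, contrasts = list(c("ACT", "ETOH")))
  f_z <- score_screen(sim$tab, sim$lib, contrasts = list(c("ACT", "ETOH")),
                      z_before_average = TRUE)
  # both orders must rank the same strong suppressors at the top
  sup <- rownames(sim$truth$s)[sim$truth$s[, "ACT"] > 0]
  top_avg <- names(sort(f_avg$delta_z[, 1], decreasing = TRUE))[1:5]
  top_z <- names(sort(f_z$delta_z[, 1], decreasing = TRUE))[1:5]
  expect_gte(length(intersect(top_avg, sup)), 4)
  expect_gte(length(intersect(top_z, sup)), 4)
})
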
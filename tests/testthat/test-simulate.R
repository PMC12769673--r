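test_that("fitness assignment bookkeeping matches the class specification", {
  lib <- build_library(1000, 1, 0, seed = 1)
  des <- small_design()
  spec <- list(ACT = list(n_suppressors = 50, n_sick = 50,
                          s_suppressor = 0.4, s_sick = -0.4))
  truth <- assign_fitness(lib, des, spec, shared_sick_genes = 20, seed = 2)
  tab <- table(truth$gene_class[, "ACT"])
  expect_equal(unname(tab["suppressor"]), 50)
  expect_equal(unname(tab["synthetic_sick"]), 70)  # 50 condition + 20 shared
  expect_equal(unname(tab["neutral"]), 880)
  expect_true(all(truth$gene_class[, "ETOH"] == "neutral"))
  expect_true(all(truth$s[, "ETOH"] == 0))
  expect_true(all(truth$s[truth$gene_class[, "ACT"] == "suppressor", "ACT"] > 0))
  expect_true(all(truth$guide_efficacy >= 0 & truth$guide_efficacy <= 1))

  # different seeds: identical class counts, different gene identities
  truth2 <- assign_fitness(lib, des, spec, shared_sick_genes = 20, seed = 3)
  expect_equal(table(truth2$gene_class[, "ACT"]), tab)
  expect_false(identical(
    rownames(truth$s)[truth$s[, "ACT"] > 0],
    rownames(truth2$s)[truth2$s[, "ACT"] > 0]))
})

test_that("all-zero class spec yields an all-neutral screen", {
  lib <- build_library(20, 2, 2, seed = 1)
  truth <- neutral_truth(lib, small_design())
  expect_true(all(truth$s == 0))
  expect_true(all(truth$gene_class == "neutral"))
})

test_that("overfull class requests are rejected", {
  lib <- build_library(10, 1, 0, seed = 1)
  expect_error(
    assign_fitness(lib, small_design(),
                   list(ACT = list(n_suppressors = 8, n_sick = 8)), seed = 1),
    "requests")
})

test_that("neutral passaging leaves relative abundances unchanged", {
  lib <- build_library(30, 2, 5, seed = 4)
  des <- small_design()
  traj <- simulate_passaging(lib, neutral_truth(lib, des), des, seed = 5)
  for (col in colnames(traj$final)) {
    expect_equal(unname(traj$final[, col]), unname(traj$initial))
  }
  expect_equal(sum(traj$initial), 1, tolerance = 1e-9)
  expect_true(all(abs(colSums(traj$final) - 1) < 1e-9))
})

test_that("selection follows the closed-form exponential factor", {
  # one suppressor at s_eff = +0.5 over D = 3 drug-arm doublings:
  # abundance ratio vs a neutral guide changes by 2^(0.5 * 3)
  lib <- build_library(10, 1, 0, seed = 1)
  des <- screen_design(conditions = c("ETOH", "ACT"), reference = "ETOH",
                       n_replicates = 1, duration_days = 3,
                       passage_interval_h = 72,
                       growth_inhibition = c(ACT = 0))
  truth <- neutral_truth(lib, des)
  truth$s["GENE00001", "ACT"] <- 0.5
  truth$guide_efficacy[] <- 1
  traj <- simulate_passaging(lib, truth, des, seed = 2)
  ratio0 <- traj$initial["GENE00001_g1"] / traj$initial["GENE00002_g1"]
  ratio1 <- traj$final["GENE00001_g1", "ACT_R1"] /
    traj$final["GENE00002_g1", "ACT_R1"]
  expect_equal(unname(ratio1 / ratio0), 2^(0.5 * 3), tolerance = 1e-12)
})

test_that("guide efficacy scales the realized selection coefficient", {
  lib <- build_library(10, 1, 0, seed = 1)
  des <- screen_design(conditions = c("ETOH", "ACT"), reference = "ETOH",
                       n_replicates = 1, duration_days = 3,
                       growth_inhibition = c(ACT = 0))
  truth <- neutral_truth(lib, des)
  truth$s["GENE00001", "ACT"] <- 0.5
  truth$guide_efficacy[] <- 1
  truth$guide_efficacy["GENE00001_g1"] <- 0.6
  traj <- simulate_passaging(lib, truth, des, seed = 2)
  ratio <- (traj$final["GENE00001_g1", "ACT_R1"] / traj$initial["GENE00001_g1"]) /
    (traj$final["GENE00002_g1", "ACT_R1"] / traj$initial["GENE00002_g1"])
  expect_equal(unname(ratio), 2^(3 * 0.5 * 0.6), tolerance = 1e-12)
})

test_that("cumulative doublings follow the growth model", {
  lib <- build_library(5, 1, 0, seed = 1)
  # untreated: 15 days at 24 h doubling = 15 doublings
  des <- small_design(growth_inhibition = c(ACT = 0.4))
  traj <- simulate_passaging(lib, neutral_truth(lib, des), des, seed = 1)
  expect_equal(unname(traj$cumulative_doublings["ETOH", 5]), 15)
  # 40% inhibition: 15 * 0.6 = 9 doublings
  expect_equal(unname(traj$cumulative_doublings["ACT", 5]), 9)
  expect_equal(unname(traj$cumulative_doublings["ACT", ]), 1.8 * (1:5))
})

test_that("larger selection coefficients strictly increase the final/initial ratio", {
  lib <- build_library(20, 1, 0, seed = 2)
  des <- small_design(n_replicates = 1)
  ratios <- sapply(c(0.1, 0.2, 0.4, 0.8), function(s) {
    truth <- neutral_truth(lib, des)
    truth$s["GENE00001", "ACT"] <- s
    truth$guide_efficacy[] <- 1
    traj <- simulate_passaging(lib, truth, des, seed = 3)
    traj$final["GENE00001_g1", "ACT_R1"] / traj$initial["GENE00001_g1"]
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("sequencing counts are multinomial with exact column totals", {
  sim <- simulate_screen(n_genes = 50, seed = 6,
                         design = small_design(reads_per_sample = 30000))
  expect_true(all(colSums(sim$tab$counts) == 30000))
  expect_equal(ncol(sim$tab$counts), 3 + 2 * 3)  # T0 x3 + 2 conditions x 3 reps
  # default depth resolves to 150 reads per guide
  sim2 <- simulate_screen(n_genes = 20, n_controls = 0, seed = 6)
  expect_true(all(colSums(sim2$tab$counts) == 150 * nrow(sim2$lib)))
})

test_that("count sampling variance matches binomial moments", {
  # uniform abundances: a single guide's count is Binomial(N, 1/G)
  n_g <- 40L
  reads <- 4000L
  lib <- build_library(n_g, 1, 0, seed = 1)
  des <- small_design(conditions = c("ETOH"), n_replicates = 1,
                      reads_per_sample = reads)
  truth <- neutral_truth(lib, des)
  traj <- simulate_passaging(lib, truth, des, seed = 1)
  traj$initial[] <- 1 / n_g
  traj$final[] <- 1 / n_g
  draws <- vapply(1:400, function(i) {
    sample_counts(traj, des, seed = i)$counts[1, "ETOH_R1"]
  }, numeric(1))
  p <- 1 / n_g
  expect_equal(mean(draws), reads * p, tolerance = 0.05)
  v_true <- reads * p * (1 - p)
  se_var <- v_true * sqrt(2 / (length(draws) - 1))
  expect_lt(abs(var(draws) - v_true), 3 * se_var)
})

test_that("identical seeds reproduce identical counts", {
  a <- simulate_screen(n_genes = 30, seed = 11)
  b <- simulate_screen(n_genes = 30, seed = 11)
  expect_identical(a$tab$counts, b$tab$counts)
  c <- simulate_screen(n_genes = 30, seed = 12)
  expect_false(identical(a$tab$counts, c$tab$counts))
})
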
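test_that("zero expansion rate returns the inherited length everywhere", {
  kin <- expansion_kinetics(base_rate = 0, subtype_multipliers = c(A = 1))
  cells <- data.frame(cell_id = paste0("c", 1:50), subtype = "A", donor = "D1")
  lens <- simulate_repeat_lengths(cells, kin, inherited = 42, seed = 1)
  expect_true(all(lens$cag_hd == 42L))
})

test_that("expansion is allele-specific: the other allele never moves", {
  kin <- expansion_kinetics(subtype_multipliers = c(A = 18))
  cells <- data.frame(cell_id = paste0("c", 1:400), subtype = "A", donor = "D1")
  lens <- simulate_repeat_lengths(cells, kin, inherited = 42,
                                  inherited_other = 17, age = 60, seed = 2)
  expect_true(all(lens$cag_other == 17L))
  expect_true(all(lens$cag_hd >= 42L))
})

test_that("faster subtypes push more cells into the long-repeat tail", {
  kin <- expansion_kinetics(subtype_multipliers = c(slow = 1, fast = 20))
  cells <- data.frame(cell_id = sprintf("c%05d", 1:6000),
                      subtype = rep(c("slow", "fast"), each = 3000),
                      donor = "D1")
  lens <- simulate_repeat_lengths(cells, kin, inherited = 42, age = 50,
                                  seed = 3)
  tail_frac <- tapply(lens$cag_hd > 100, cells$subtype, mean)
  expect_gt(tail_frac[["fast"]], tail_frac[["slow"]])
  expect_gt(tail_frac[["fast"]], 0.01)
})

test_that("fast subtypes develop the right-skewed armadillo distribution", {
  kin <- expansion_kinetics(subtype_multipliers = c(mid = 4, fast = 18))
  cells <- data.frame(cell_id = sprintf("c%05d", 1:8000),
                      subtype = rep(c("mid", "fast"), each = 4000),
                      donor = "D1")
  lens <- simulate_repeat_lengths(cells, kin, inherited = 42, age = 60,
                                  seed = 4)
  fast <- lens$cag_hd[cells$subtype == "fast"]
  mid <- lens$cag_hd[cells$subtype == "mid"]
  expect_gt(mean(fast > 100), 0.01)
  expect_gt(mean(fast), median(fast))   # right skew
  expect_gt(var(fast), var(mid))        # variance grows with the multiplier
})

test_that("tail fractions are monotone in the subtype multiplier", {
  mults <- c(a = 1, b = 4, c = 18)
  acc <- matrix(0, 10, 3, dimnames = list(NULL, names(mults)))
  kin <- expansion_kinetics(subtype_multipliers = mults)
  cells <- data.frame(cell_id = sprintf("c%04d", 1:1800),
                      subtype = rep(names(mults), each = 600), donor = "D1")
  for (s in 1:10) {
    lens <- simulate_repeat_lengths(cells, kin, inherited = 42, age = 50,
                                    seed = 100 + s)
    acc[s, ] <- tapply(lens$cag_hd > 80, cells$subtype, mean)[names(mults)]
  }
  avg <- colMeans(acc)
  expect_true(all(diff(avg) >= 0))
})

test_that("the repeat-length simulator is deterministic under a fixed seed", {
  kin <- expansion_kinetics(subtype_multipliers = c(A = 6))
  cells <- data.frame(cell_id = paste0("c", 1:200), subtype = "A", donor = "D1")
  a <- simulate_repeat_lengths(cells, kin, inherited = 43, seed = 11)
  b <- simulate_repeat_lengths(cells, kin, inherited = 43, seed = 11)
  expect_identical(a, b)
})

test_that("kinetics constructor rejects an over-coarse time step", {
  expect_error(expansion_kinetics(rate_cap = 20, steps_per_year = 12),
               "steps_per_year")
})

test_that("phase D entry states follow the hazard", {
  lengths <- setNames(c(rep(120, 500), rep(300, 2000)),
                      sprintf("c%04d", 1:2500))
  expect_false(any(simulate_phase_d_states(lengths, 0, seed = 1)))
  h1 <- hazard_step(250, c(0, 1))
  st <- simulate_phase_d_states(lengths, h1, seed = 1)
  expect_true(all(st[lengths > 250]))
  expect_false(any(st[lengths <= 250]))

  # empirical fraction at hazard 0.5 stays inside the binomial 99% CI
  h2 <- hazard_step(250, c(0, 0.5))
  st <- simulate_phase_d_states(lengths, h2, seed = 42)
  n <- sum(lengths > 250)
  ci <- qbinom(c(0.005, 0.995), n, 0.5) / n
  frac <- mean(st[lengths > 250])
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])

  expect_error(simulate_phase_d_states(lengths, 1.2), "\\[0, 1\\]")
  expect_error(hazard_step(c(250, 150), c(0, .1, .2)), "increasing")
})

test_that("a phase C decreasing gene attenuates by the closed-form ratio", {
  # slope -0.01 per unit beyond 150: cells at 250 vs 150 CAGs differ by
  # a factor exp(-0.01 * 100) = exp(-1)
  tr <- expression_truth(subtypes = "A", n_genes = 40, n_cplus = 0,
                         n_cminus = 1, n_phased = 0, cminus_slope = -0.01,
                         seed = 5)
  g <- tr$panels$cminus
  cells <- data.frame(cell_id = sprintf("c%05d", 1:6000), subtype = "A",
                      donor = "D1", stringsAsFactors = FALSE)
  lengths <- setNames(rep(c(150, 250), each = 3000), cells$cell_id)
  sim <- simulate_expression(cells, lengths, truth = tr, donor_sd = 0,
                             seed = 6)
  per100k <- as.numeric(sim$counts[g, ]) * 1e5 / sim$cells$total_umis
  ratio <- mean(per100k[lengths == 250]) / mean(per100k[lengths == 150])
  expect_equal(ratio, exp(-1), tolerance = 0.08)
})

test_that("a de-repressed phase D gene emits at rate x N / 100k", {
  tr <- expression_truth(subtypes = "A", n_genes = 30, n_cplus = 0,
                         n_cminus = 0, n_phased = 5, derep_rate = 10,
                         seed = 7)
  cells <- data.frame(cell_id = sprintf("c%05d", 1:4000), subtype = "A",
                      donor = "D1", stringsAsFactors = FALSE)
  lengths <- setNames(rep(300, 4000), cells$cell_id)
  state <- setNames(rep(TRUE, 4000), cells$cell_id)
  sim <- simulate_expression(cells, lengths, state, tr, donor_sd = 0, seed = 8)
  g <- tr$panels$phaseD[1]
  # library sizes are ~20k, so the expected count per cell is ~2
  expected <- mean(10 * sim$cells$total_umis / 1e5)
  expect_equal(mean(sim$counts[g, ]), expected, tolerance = 0.05)
})

test_that("with no effects, normalized expression is flat in CAG length", {
  tr <- expression_truth(subtypes = "A", n_genes = 40, n_cplus = 0,
                         n_cminus = 0, n_phased = 0, seed = 9)
  cells <- data.frame(cell_id = sprintf("c%05d", 1:2000), subtype = "A",
                      donor = "D1", stringsAsFactors = FALSE)
  lengths <- setNames(round(runif(2000, 40, 400)), cells$cell_id)
  sim <- simulate_expression(cells, lengths, truth = tr, donor_sd = 0,
                             seed = 10)
  g <- tr$genes$gene[which.max(exp(tr$baseline[, 1]))]
  y <- as.numeric(sim$counts[g, ]) * 1e5 / sim$cells$total_umis
  fit <- summary(stats::lm(y ~ lengths))$coefficients
  ci <- fit["lengths", 1] + c(-3, 3) * fit["lengths", 2]
  expect_gte(ci[2], 0)
  expect_lte(ci[1], 0)
})

test_that("library sizes are consistent with the per-100k normalization", {
  tr <- expression_truth(subtypes = "A", n_genes = 60, n_cplus = 5,
                         n_cminus = 5, n_phased = 10, seed = 11)
  cells <- data.frame(cell_id = sprintf("c%04d", 1:400), subtype = "A",
                      donor = "D1", stringsAsFactors = FALSE)
  lengths <- setNames(rep(50, 400), cells$cell_id)
  sim <- simulate_expression(cells, lengths, truth = tr, seed = 12)
  # realized totals track the drawn targets (mean ~ exp(meanlog + sd^2/2))
  expect_equal(mean(sim$cells$total_umis), 20000 * exp(0.35^2 / 2),
               tolerance = 0.1)
})

test_that("village study needs both donor groups and respects survival 1", {
  expect_error(simulate_village_study(0, 10), "both groups")
  v <- simulate_village_study(12, 12, counts_per_donor = 5000, seed = 13)
  rel <- relative_abundance(v$abundance)
  sr <- survival_ratios(rel, v$conditions, n_boot = 200, seed = 13)
  expect_true(all(abs(sr$survival_ratio - 1) < 0.25))
})

test_that("the full dataset generator is reproducible and coherent", {
  a <- simulate_dataset(n_cells = 250, seed = 21,
                        truth_args = list(n_genes = 60, n_cplus = 8,
                                          n_cminus = 8, n_phased = 8))
  b <- simulate_dataset(n_cells = 250, seed = 21,
                        truth_args = list(n_genes = 60, n_cplus = 8,
                                          n_cminus = 8, n_phased = 8))
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$cells, b$cells)
  # control donors never carry a disease-allele measurement
  expect_true(all(is.na(a$cells$cag_hd[a$cells$condition == "control"])))
  # the truth ledger keeps lengths that the observed table masked
  masked <- is.na(a$cells$cag_hd) & a$cells$condition == "HD"
  expect_true(all(!is.na(a$truth$lengths[a$cells$cell_id[masked]])))
})
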
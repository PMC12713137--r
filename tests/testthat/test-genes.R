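test_that("hinge matches its brute-force transcription on an exhaustive grid", {
  cag <- 1:600
  got <- hinge(cag, 150, 500)
  oracle <- numeric(600)
  for (i in seq_along(cag)) {
    oracle[i] <- if (cag[i] < 150) 0 else min(cag[i], 500) - 150
  }
  expect_identical(got, oracle)
  expect_identical(hinge(c(100, 160, 600)), c(0, 10, 350))
  expect_error(hinge(100, m = 500, n = 150), "m < n")
})

test_that("phase D probability matches the logistic transcription", {
  scores <- seq(0, 100, by = 0.25)
  for (par in list(c(2, 2), c(0.7, 5))) {
    got <- phase_d_prob(scores, par[1], par[2])
    oracle <- 1 / (1 + exp(-par[1] * (scores - par[2])))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  expect_equal(phase_d_prob(2, S = 2, M = 2), 0.5)
  expect_equal(phase_d_prob(0, S = 2, M = 2), 1 / (1 + exp(4)),
               tolerance = 1e-12)
  # strictly increasing, approaching 1
  p <- phase_d_prob(c(1, 5, 20, 60), 2, 2)
  expect_true(all(diff(p) > 0))
  expect_gt(p[4], 1 - 1e-12)
})

test_that("the panel score is total panel UMIs per 100k", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 2), x = c(1, 1, 5),
                            dims = c(3, 3),
                            dimnames = list(c("p1", "p2", "g"),
                                            c("c1", "c2", "c3")))
  sc <- phase_d_score(m, c("p1", "p2"), total_umis = c(20000, 100000, 50000))
  expect_equal(unname(sc), c(10, 0, 0))
  expect_equal(phase_d_score(m, c("p1", "p2"),
                             total_umis = c(1e5, 1e5, 1e5))[["c1"]], 2)
  expect_error(phase_d_score(m, "absent"), "absent")
  expect_error(phase_d_score(m, "p1", total_umis = c(0, 1, 1)), "zero total")
})

test_that("downsampling keeps the right strata", {
  cells <- data.frame(cell_id = paste0("c", 1:9),
                      cag_hd = c(30, 35, 36, 50, 100, 101, 150, 200, 500))
  kept <- downsample_for_fitting(cells, keep = 0, seed = 1)
  # keep = 0 removes exactly the (35, 100] stratum
  expect_setequal(kept$cag_hd, c(30, 35, 101, 150, 200, 500))

  big <- data.frame(cell_id = seq_len(10000), cag_hd = rep(50, 10000))
  kept <- downsample_for_fitting(big, keep = 0.10, seed = 2)
  ci <- qbinom(c(5e-4, 1 - 5e-4), 10000, 0.10)
  expect_gte(nrow(kept), ci[1])
  expect_lte(nrow(kept), ci[2])

  all_high <- data.frame(cell_id = 1:100, cag_hd = rep(200, 100))
  expect_identical(nrow(downsample_for_fitting(all_high, seed = 3)), 100L)
  expect_identical(downsample_for_fitting(cells, seed = 7),
                   downsample_for_fitting(cells, seed = 7))
  expect_error(downsample_for_fitting(data.frame(cag_hd = NA_real_)),
               "CAG measurement")
})

test_that("the per-gene NB fit recovers an injected hinge slope", {
  fx <- gene_fit_fixture(n_cells = 3000,
                         truth_args = list(cminus_slope = -0.01,
                                           cplus_slope = 0.01),
                         seed = 51)
  spec <- gene_model_spec(panel = fx$truth$panels$phaseD)
  for (g in fx$truth$panels$cminus[1:2]) {
    fit <- fit_gene_nbr(g, fx$counts, fx$cells, spec)
    expect_true(fit$converged)
    expect_equal(fit$beta_hinge, -0.01, tolerance = 0.3)
    expect_lt(fit$p_hinge, 1e-6)
  }
  g <- fx$truth$panels$cplus[1]
  fit <- fit_gene_nbr(g, fx$counts, fx$cells, spec)
  expect_equal(fit$beta_hinge, 0.01, tolerance = 0.3)
})

test_that("phase D effects land on the phase D coefficient, not the hinge", {
  withr::with_seed(52, {
    truth <- expression_truth(subtypes = c("A", "B", "C"), n_genes = 60,
                              n_cplus = 0, n_cminus = 0, n_phased = 10,
                              derep_rate = 10)
    g <- truth$panels$phaseD[1]
    # give the fitted gene a measurable leak so its MLE is finite; the
    # score panel excludes it (leave-one-out) to avoid self-reference
    truth$genes$baseline_rate[truth$genes$gene == g] <- 0.1
    n <- 2500
    cells <- data.frame(
      cell_id = sprintf("c%05d", 1:n),
      donor = sample(paste0("D", 1:4), n, TRUE),
      region = sample(c("BA4", "BA32"), n, TRUE),
      subtype = sample(truth$subtypes, n, TRUE), stringsAsFactors = FALSE)
    cells$subcluster <- cells$subtype
    cells$cag_hd <- sample(c(round(runif(1500, 40, 100)),
                             round(runif(1000, 160, 450))))
    lengths <- setNames(cells$cag_hd, cells$cell_id)
    st <- simulate_phase_d_states(lengths, hazard_step(150, c(0, 0.25)))
    sim <- simulate_expression(cells, lengths, st, truth)
    spec <- gene_model_spec(panel = setdiff(truth$panels$phaseD, g))
    fit <- fit_gene_nbr(g, sim$counts, sim$cells, spec)
    expect_true(fit$converged)
    expect_lt(fit$p_phased, 1e-10)
    expect_gt(exp(fit$beta_phased), 10)
    # no true hinge effect: the de-repression must not masquerade as phase C
    expect_gt(fit$p_hinge, 1e-3)
  })
})

test_that("gene classification applies sign, FDR and fold-change rules", {
  fits <- data.frame(
    gene = c("up", "down", "flat", "zero", "d_strong", "d_weak"),
    beta_hinge = c(0.01, -0.01, 0.001, 0, 0, 0),
    q_hinge = c(1e-4, 1e-4, 0.5, 1e-6, 0.9, 0.9),
    beta_phased = c(0, 0, 0, 0, log(40), log(5)),
    q_phased = c(0.9, 0.9, 0.9, 0.9, 1e-5, 1e-5),
    converged = TRUE, stringsAsFactors = FALSE)
  sets <- classify_phase_genes(fits, fdr_c = 0.05, fdr_d = 0.001, fc_d = 10)
  expect_identical(sets$cplus, "up")
  expect_identical(sets$cminus, "down")
  expect_identical(sets$phased, "d_strong")
  # beta_hinge exactly zero is never phase C, whatever its q-value
  expect_false("zero" %in% c(sets$cplus, sets$cminus))
  null_fits <- fits
  null_fits$q_hinge <- 0.9
  null_fits$q_phased <- 0.9
  empty <- classify_phase_genes(null_fits)
  expect_identical(lengths(empty), c(cplus = 0L, cminus = 0L, phased = 0L))
})

test_that("median fold-change is ~1 at baseline and exp(-1) at the far end", {
  fx <- gene_fit_fixture(n_cells = 4000,
                         truth_args = list(cminus_slope = -0.005,
                                           n_cminus = 8, n_cplus = 0),
                         high_range = c(345, 355), seed = 53)
  traj <- median_fc_trajectory(fx$counts, fx$cells,
                               fx$truth$panels$cminus,
                               subtype_col = "subtype")
  base <- traj$median_fc[traj$cag_hd <= 100]
  far <- traj$median_fc[traj$cag_hd >= 345]
  # count noise biases a median of ratios slightly below 1 at baseline
  expect_equal(median(base), 1, tolerance = 0.2)
  # slope -0.005 over ~200 units beyond onset: fold-change exp(-1)
  # relative to the baseline cells (the ratio cancels the noise bias)
  expect_equal(median(far) / median(base), exp(-1), tolerance = 0.12)
})

test_that("genes below the detection floor are excluded from the median", {
  fx <- gene_fit_fixture(n_cells = 500, seed = 54)
  det <- Matrix::rowMeans(fx$counts[, fx$cells$cell_id] > 0)
  rare <- names(which(det < 0.5))
  common <- names(which(det >= 0.99))
  expect_gt(length(rare), 0)
  traj <- median_fc_trajectory(fx$counts, fx$cells,
                               c(common[1:3], rare[1]),
                               detected_floor = 0.90)
  expect_true(all(traj$n_genes == 3))
  expect_error(median_fc_trajectory(fx$counts, fx$cells, rare[1],
                                    detected_floor = 0.90), "90%")
})

test_that("cross-context comparison is exact on identical fits", {
  fits <- data.frame(gene = paste0("g", 1:6),
                     beta_hinge = c(-0.01, 0.02, -0.005, 0.004, 0.01, 0),
                     p_hinge = c(1e-20, 1e-15, 1e-12, 0.5, 1e-11, 0.9),
                     converged = TRUE, stringsAsFactors = FALSE)
  cmp <- compare_phase_c(fits, fits)
  expect_equal(cmp$correlation, 1)
  expect_equal(cmp$sign_agreement, 1)
  expect_equal(cmp$n_genes, 4L)  # genes at p < 1e-10 in either context
  other <- fits
  other$gene <- paste0("h", 1:6)
  expect_error(compare_phase_c(fits, other), "disjoint")
})

test_that("shared phase C truth yields concordant slopes across contexts", {
  mk <- function(seed) {
    fx <- gene_fit_fixture(n_cells = 1800,
                           truth_args = list(cminus_slope = -0.012,
                                             cplus_slope = 0.012,
                                             n_cminus = 6, n_cplus = 6,
                                             n_phased = 0),
                           seed = seed)
    spec <- gene_model_spec()
    genes <- c(fx$truth$panels$cminus, fx$truth$panels$cplus)
    fit_gene_models(fx$counts, fx$cells, spec, genes = genes)
  }
  # same truth object (same seed-built program), independent cells/noise
  cmp <- compare_phase_c(mk(61), mk(62), p_cut = 1e-6)
  expect_gte(cmp$n_genes, 6)
  expect_gt(cmp$correlation, 0.8)
  expect_equal(cmp$sign_agreement, 1)
})
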
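test_that("the phase D call is a strict monotone threshold on the score", {
  expect_false(call_phase_d(0))
  expect_false(call_phase_d(2))  # at the midpoint, prob = 0.5 exactly
  expect_true(call_phase_d(2.01))
  scores <- seq(0, 50, by = 0.5)
  calls <- call_phase_d(scores)
  expect_true(all(diff(as.integer(calls)) >= 0))  # monotone in score
})

test_that("phase D calls recover simulated crisis states", {
  # leave-one-out not needed here: the score uses the whole panel, as in
  # the analysis; recall/precision are judged against the generator truth
  withr::with_seed(71, {
    truth <- expression_truth(subtypes = "A", n_genes = 80, n_cplus = 0,
                              n_cminus = 0, n_phased = 20, derep_rate = 10)
    n <- 3000
    cells <- data.frame(cell_id = sprintf("c%05d", 1:n), subtype = "A",
                        donor = "D1", stringsAsFactors = FALSE)
    cells$cag_hd <- round(runif(n, 160, 450))
    lengths <- setNames(cells$cag_hd, cells$cell_id)
    st <- simulate_phase_d_states(lengths, 0.3)
    sim <- simulate_expression(cells, lengths, st, truth)
    sc <- phase_d_score(sim$counts, truth$panels$phaseD,
                        sim$cells$total_umis)
    called <- call_phase_d(sc)
    recall <- sum(called & st) / sum(st)
    precision <- sum(called & st) / sum(called)
    expect_gt(recall, 0.9)
    expect_gt(precision, 0.9)
  })
})

test_that("entry fractions by bin track the generator hazard", {
  withr::with_seed(72, {
    n <- 4000
    cells <- data.frame(cell_id = sprintf("c%05d", 1:n),
                        cag_hd = round(runif(n, 151, 600)))
    haz <- hazard_step(c(150, 250, 350, 500), c(0, 0.05, 0.25, 0.5, 0.8))
    st <- simulate_phase_d_states(setNames(cells$cag_hd, cells$cell_id), haz)
    # scores that the call maps back onto the true state
    scores <- setNames(ifelse(st, 50, 0), cells$cell_id)
    s <- entry_fraction_by_bin(cells, scores)
    expect_equal(s$fraction, c(0.05, 0.25, 0.5, 0.8), tolerance = 0.25)
    expect_true(all(diff(s$fraction) > 0))
    expect_true(all(s$lo <= s$fraction & s$fraction <= s$hi))
    # a single all-covering bin reproduces the overall entry rate
    one <- entry_fraction_by_bin(cells, scores, bins = c(0, Inf))
    expect_equal(one$fraction, mean(st))
    expect_error(entry_fraction_by_bin(cells, scores, bins = c(250, 150)),
                 "increasing")
  })
})

test_that("hazard zero gives empty bins everywhere", {
  cells <- data.frame(cell_id = paste0("c", 1:500),
                      cag_hd = round(runif(500, 160, 600)))
  scores <- setNames(rep(0, 500), cells$cell_id)
  s <- entry_fraction_by_bin(cells, scores)
  expect_true(all(s$fraction[s$n > 0] == 0))
})

test_that("crisis structure reports the bimodal score pattern", {
  cells <- data.frame(cell_id = paste0("c", 1:100),
                      cag_hd = c(rep(100, 10), rep(300, 90)))
  # 80 quiescent long-repeat cells, 10 in crisis
  scores <- setNames(c(rep(0, 10), rep(0.5, 80), rep(c(12, 4), 5)),
                     cells$cell_id)
  cs <- crisis_structure(cells, scores)
  expect_equal(cs$n_cells, 90L)  # short-repeat cells excluded
  expect_equal(cs$fraction_quiescent, 80 / 90)
  expect_equal(cs$n_above_mid, 10L)
  expect_equal(cs$fraction_high_given_mid, 0.5)
  expect_error(crisis_structure(cells[1:10, ], scores), "CAG length > 150")

  # distinct panel-gene counting
  m <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 1), x = c(1, 2, 1),
                            dims = c(4, 2),
                            dimnames = list(paste0("p", 1:4),
                                            c("c11", "c12")))
  cells2 <- data.frame(cell_id = c("c11", "c12"), cag_hd = c(300, 300))
  cs2 <- crisis_structure(cells2, setNames(c(20, 0), cells2$cell_id),
                          counts = m, panel = paste0("p", 1:4))
  expect_identical(unname(cs2$distinct_genes), c(3L, 0L))
})

test_that("crisis fractions are invariant to cell order and depth scaling", {
  withr::with_seed(73, {
    cells <- data.frame(cell_id = paste0("c", 1:400),
                        cag_hd = round(runif(400, 151, 500)))
    scores <- setNames(rexp(400, 1 / 3), cells$cell_id)
    a <- crisis_structure(cells, scores)
    perm <- sample(400)
    b <- crisis_structure(cells[perm, ], scores)
    expect_equal(a$fraction_quiescent, b$fraction_quiescent)
    expect_equal(a$fraction_high_given_mid, b$fraction_high_given_mid)
  })
})

test_that("magnitude does not track length when the generator decouples them", {
  withr::with_seed(74, {
    n <- 800
    cells <- data.frame(cell_id = paste0("c", 1:n),
                        cag_hd = round(runif(n, 160, 500)))
    # crisis magnitude independent of length
    scores <- setNames(ifelse(runif(n) < 0.4, rexp(n, 1 / 20) + 3, 0),
                       cells$cell_id)
    r <- magnitude_vs_length(cells, scores, n_perm = 500, seed = 1)
    expect_identical(r$status, "ok")
    expect_gt(r$p_perm, 0.01)
    expect_lt(abs(r$rho), 0.15)
  })
})

test_that("magnitude-length coupling is detected when present", {
  withr::with_seed(75, {
    n <- 1000
    cag <- round(runif(n, 160, 500))
    entered <- runif(n) < 0.5
    # de-repressed rate doubles per 100 CAG units
    scores <- setNames(ifelse(entered, 3 + rexp(n, 1) * 2^(cag / 100), 0),
                       paste0("c", 1:n))
    cells <- data.frame(cell_id = paste0("c", 1:n), cag_hd = cag)
    r <- magnitude_vs_length(cells, scores, n_perm = 500, seed = 2)
    expect_gt(r$rho, 0.2)
    expect_lt(r$p_perm, 0.05)
  })
})

test_that("constant scores give correlation zero and small samples bail out", {
  cells <- data.frame(cell_id = paste0("c", 1:60),
                      cag_hd = round(seq(160, 500, length.out = 60)))
  scores <- setNames(rep(10, 60), cells$cell_id)
  r <- magnitude_vs_length(cells, scores, seed = 3)
  expect_equal(r$rho, 0)
  few <- magnitude_vs_length(cells[1:5, ], scores[1:5], seed = 4)
  expect_identical(few$status, "insufficient")
})
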
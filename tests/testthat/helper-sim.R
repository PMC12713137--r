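# shared fixture builders; everything is generated in code under fixed seeds

toy_counts <- function() {
  m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(5, 2),
                            dims = c(3, 2),
                            dimnames = list(c("g1", "g2", "g3"),
                                            c("c1", "c2")))
  methods::as(m, "CsparseMatrix")
}

toy_cells <- function() {
  data.frame(cell_id = c("c1", "c2"), donor = c("D1", "D1"),
             region = c("BA4", "BA4"), supercluster = "Exc",
             cluster = c("k1", "k2"), subclass = c("L6b", "L5IT"),
             condition = c("HD", "HD"), total_umis = c(5L, 2L),
             cag_hd = c(120L, NA), cag_other = c(18L, 18L),
             inherited_cag_hd = c(42L, 42L), inherited_cag_other = c(18L, 18L),
             stringsAsFactors = FALSE)
}

# cells spanning the phase C repeat-length range, with expression simulated
# from a small ground-truth program; kinetics are bypassed so gene-model
# tests control the length composition directly
gene_fit_fixture <- function(n_cells = 3000, truth_args = list(),
                             frac_high = 0.4, hazard = 0, seed = 1,
                             n_donors = 4, n_regions = 2,
                             high_range = c(160, 450)) {
  withr::with_seed(seed, {
    defaults <- list(subtypes = c("A", "B", "C"), n_genes = 60, n_cplus = 5,
                     n_cminus = 5, n_phased = 10)
    truth <- do.call(expression_truth,
                     utils::modifyList(defaults, truth_args))
    n_hi <- round(n_cells * frac_high)
    cag <- sample(c(round(runif(n_cells - n_hi, 40, 100)),
                    round(runif(n_hi, high_range[1], high_range[2]))))
    cells <- data.frame(
      cell_id = sprintf("c%05d", seq_len(n_cells)),
      donor = sample(paste0("D", seq_len(n_donors)), n_cells, TRUE),
      region = sample(c("BA4", "BA32")[seq_len(n_regions)], n_cells, TRUE),
      subtype = sample(truth$subtypes, n_cells, TRUE),
      cag_hd = cag, stringsAsFactors = FALSE)
    cells$subcluster <- cells$subtype
    lengths <- setNames(cells$cag_hd, cells$cell_id)
    state <- simulate_phase_d_states(lengths, hazard)
    sim <- simulate_expression(cells, lengths, state, truth)
    list(truth = truth, cells = sim$cells, counts = sim$counts,
         state = state)
  })
}
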
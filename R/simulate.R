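#' Kinetic parameters of the two-phase somatic expansion process
#'
#' Somatic CAG-repeat expansion is modeled as a discrete-time pure-birth
#' process on repeat length: in each time step a cell's tract gains one
#' repeat unit with probability `rate / steps_per_year`, where the rate
#' (expansions per cell per year) grows exponentially with current length
#' during phase A — `base_rate * length_slope^(len - inherited)`, times the
#' cell type's multiplier and a per-cell log-normal frailty — and is
#' multiplied by a constant boost once the tract passes the phase B
#' threshold (about 90 units).  Two bounds keep the process well posed:
#' the exponential length dependence stops growing at the phase B
#' threshold, and the phase A rate saturates at `rate_cap` (expansion
#' machinery saturation), so the per-step probability never exceeds
#' `rate_cap * phaseB_boost / steps_per_year`; construction fails with an
#' instruction to use a finer time step if that bound exceeds one.
#' Lengths are absorbed at `max_cag`, the longest tract the assay
#' resolves.
#'
#' The per-cell frailty (`cell_rate_sd`) models stable cell-to-cell
#' variation in repeat-expansion propensity (e.g. mismatch-repair
#' activity); it is what spreads a fast subtype into the characteristic
#' armadillo shape — a dense body of cells at moderate lengths plus a
#' minority that crossed the phase B threshold and raced ahead.
#'
#' @param base_rate Expansions per cell per year at the inherited length.
#' @param length_slope Multiplicative rate increase per repeat unit gained
#'   (must be >= 1).
#' @param phaseB_threshold Repeat length at which expansion accelerates.
#' @param phaseB_boost Multiplicative acceleration once length exceeds the
#'   threshold (>= 1).
#' @param rate_cap Saturation of the phase A rate, expansions per year.
#' @param cell_rate_sd SD (log scale) of the per-cell rate frailty; the
#'   frailty is log-normal with mean 1, and 0 disables it.
#' @param subtype_multipliers Named positive vector: per-cell-type rate
#'   multipliers (pyramidal types differ up to ~18-fold).
#' @param region_multipliers Optional named positive vector of per-region
#'   multipliers (cortical areas differ only up to ~1.3-fold).
#' @param allele_specific If `TRUE` (default) only the disease allele
#'   expands; the other allele keeps its inherited length.
#' @param steps_per_year Time resolution of the discrete process.
#' @param max_cag Absorbing cap on repeat length.
#' @return A list of class `expansion_kinetics`.
#' @export
#' @examples
#' kin <- expansion_kinetics(subtype_multipliers = c(L5IT = 1, L6b = 18))
expansion_kinetics <- function(base_rate = 0.025, length_slope = 1.025,
                               phaseB_threshold = 90, phaseB_boost = 2,
                               rate_cap = 4, cell_rate_sd = 0.6,
                               subtype_multipliers = c(default = 1),
                               region_multipliers = NULL,
                               allele_specific = TRUE,
                               steps_per_year = 12, max_cag = 600) {
  if (base_rate < 0) stop("'base_rate' must be non-negative")
  if (length_slope < 1) stop("'length_slope' must be >= 1")
  if (phaseB_boost < 1) stop("'phaseB_boost' must be >= 1")
  if (rate_cap <= 0) stop("'rate_cap' must be positive")
  if (cell_rate_sd < 0) stop("'cell_rate_sd' must be non-negative")
  if (any(subtype_multipliers <= 0))
    stop("all subtype multipliers must be positive")
  if (!is.null(region_multipliers) && any(region_multipliers <= 0))
    stop("all region multipliers must be positive")
  if (is.null(names(subtype_multipliers)))
    stop("'subtype_multipliers' must be named by subtype")
  if (rate_cap * phaseB_boost / steps_per_year > 1)
    stop("per-step expansion probability exceeds 1 (",
         signif(rate_cap * phaseB_boost / steps_per_year, 3),
         "); increase 'steps_per_year' for a finer time step")
  structure(list(base_rate = base_rate, length_slope = length_slope,
                 phaseB_threshold = phaseB_threshold,
                 phaseB_boost = phaseB_boost,
                 rate_cap = rate_cap, cell_rate_sd = cell_rate_sd,
                 subtype_multipliers = subtype_multipliers,
                 region_multipliers = region_multipliers,
                 allele_specific = allele_specific,
                 steps_per_year = steps_per_year, max_cag = max_cag),
            class = "expansion_kinetics")
}

#' Simulate per-cell somatic CAG-repeat lengths
#'
#' Integrates the two-phase birth process of [expansion_kinetics()] over a
#' lifetime, cell by cell.  Fast subtypes develop the characteristic
#' right-skewed ("armadillo") length distribution: a dense body of cells at
#' moderate expansions and a long tail of cells that crossed the phase B
#' threshold and accelerated to far greater lengths.
#'
#' @param cells Data.frame with columns `subtype` and `donor` (and
#'   optionally `cell_id`, `region`, `age`).  Subtype and region values must
#'   appear in the kinetics multiplier tables (subtypes absent from the
#'   table get multiplier 1 only if a `default` entry exists).
#' @param kinetics An [expansion_kinetics()] object.
#' @param inherited Inherited disease-allele length: a single value or a
#'   named per-donor vector (>= 36 repeat units).
#' @param inherited_other Inherited length of the non-disease allele.
#' @param age Years of integration (single value or per-cell).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return Data.frame with columns `cell_id`, `cag_hd`, `cag_other`.
#' @export
simulate_repeat_lengths <- function(cells, kinetics, inherited,
                                    inherited_other = 18, age = 60,
                                    seed = NULL) {
  stopifnot(inherits(kinetics, "expansion_kinetics"))
  if (!"subtype" %in% names(cells)) stop("'cells' needs a 'subtype' column")
  n <- nrow(cells)
  if (n == 0L) stop("no cells supplied")
  if (any(age <= 0)) stop("'age' must be positive")
  cell_id <- if (!is.null(cells$cell_id)) as.character(cells$cell_id)
             else sprintf("cell%06d", seq_len(n))
  if (any(inherited < 36))
    stop("inherited disease-allele lengths must be >= 36 repeat units")
  inh <- if (length(inherited) == 1L && is.null(names(inherited)))
    rep(as.numeric(inherited), n)
  else {
    if (is.null(cells$donor)) stop("per-donor 'inherited' needs a donor column")
    miss <- setdiff(unique(as.character(cells$donor)), names(inherited))
    if (length(miss)) stop("no inherited length for donor(s): ",
                           paste(miss, collapse = ", "))
    as.numeric(inherited[as.character(cells$donor)])
  }
  mult <- lookup_multiplier(kinetics$subtype_multipliers,
                            as.character(cells$subtype), "subtype")
  if (!is.null(kinetics$region_multipliers)) {
    if (is.null(cells$region))
      stop("kinetics has region multipliers but 'cells' has no region column")
    mult <- mult * lookup_multiplier(kinetics$region_multipliers,
                                     as.character(cells$region), "region")
  }
  spy <- kinetics$steps_per_year
  ages <- rep_len(age, n)
  n_steps <- ceiling(ages * spy)
  integrate_allele <- function(start, mult, frailty) {
    len <- start
    for (s in seq_len(max(n_steps))) {
      active <- s <= n_steps & len < kinetics$max_cag
      if (!any(active)) break
      la <- len[active]
      rate <- pmin(
        kinetics$base_rate *
          kinetics$length_slope^(pmin(la, kinetics$phaseB_threshold) -
                                   start[active]) *
          mult[active] * frailty[active],
        kinetics$rate_cap) *
        ifelse(la > kinetics$phaseB_threshold, kinetics$phaseB_boost, 1)
      len[active] <- la + (runif(sum(active)) < rate / spy)
    }
    len
  }
  run <- function() {
    frailty <- if (kinetics$cell_rate_sd > 0)
      rlnorm(n, -kinetics$cell_rate_sd^2 / 2, kinetics$cell_rate_sd)
    else rep(1, n)
    len <- integrate_allele(inh, mult, frailty)
    other <- if (kinetics$allele_specific) rep_len(inherited_other, n)
    else integrate_allele(rep_len(inherited_other, n), mult, frailty)
    data.frame(cell_id = cell_id, cag_hd = as.integer(len),
               cag_other = as.integer(other), stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

lookup_multiplier <- function(table, keys, what) {
  idx <- match(keys, names(table))
  if (anyNA(idx)) {
    if ("default" %in% names(table))
      idx[is.na(idx)] <- match("default", names(table))
    else stop("no ", what, " multiplier for: ",
              paste(unique(keys[is.na(idx)]), collapse = ", "))
  }
  unname(table[idx])
}

#' Step-function hazard of phase D entry
#'
#' Builds a hazard function mapping CAG length to the probability that a
#' cell with that length has entered the phase D de-repression crisis.
#' With `k` breaks, `probs` has `k + 1` values; value `i + 1` applies on the
#' half-open interval `(breaks[i], breaks[i+1]]`.
#'
#' @param breaks Strictly increasing CAG lengths.
#' @param probs Probabilities, length `length(breaks) + 1`, non-decreasing.
#' @return A function of CAG length.
#' @export
#' @examples
#' h <- hazard_step(c(150, 250), c(0, 0.05, 0.5))
#' h(c(100, 200, 400))
hazard_step <- function(breaks, probs) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("'breaks' must be strictly increasing")
  if (length(probs) != length(breaks) + 1L)
    stop("'probs' must have length(breaks) + 1 values")
  if (any(probs < 0 | probs > 1)) stop("hazard probabilities must be in [0, 1]")
  force(breaks); force(probs)
  function(len) probs[findInterval(len, breaks, left.open = FALSE) + 1L]
}

#' Simulate which cells have entered phase D
#'
#' Independent Bernoulli draws with a length-dependent hazard: the entry
#' probability is near zero below 150 repeat units and rises with further
#' expansion.
#'
#' @param lengths Named numeric vector of CAG lengths (names = cell ids).
#' @param hazard A function of length returning an entry probability, a
#'   single probability, or the output of [hazard_step()].
#' @param seed Optional integer seed.
#' @return Named logical vector of phase D states.
#' @export
simulate_phase_d_states <- function(lengths, hazard, seed = NULL) {
  if (is.null(names(lengths))) stop("'lengths' must be named by cell id")
  p <- if (is.function(hazard)) hazard(lengths) else rep_len(hazard, length(lengths))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("hazard must give probabilities in [0, 1] for every observed length")
  draw <- function() setNames(runif(length(lengths)) < p, names(lengths))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Cortical pyramidal subtypes used by the default generator
#'
#' The eight glutamatergic subclasses named by layer and projection class.
#' @export
default_subtypes <- c("L2/3IT", "L4IT", "L5IT", "L6IT", "L5ET",
                      "L5/6NP", "L6CT", "L6b")

#' Default subtype expansion-rate multipliers
#'
#' Qualitative ordering follows the field: deep-layer L6b and
#' near-projecting types expand fastest (the span is ~18-fold), L5IT is
#' among the slowest pyramidal types, interneurons slower still.
#' @export
default_multipliers <- c("L6b" = 18, "L5/6NP" = 10, "L6CT" = 4, "L5ET" = 3,
                         "L6IT" = 2.5, "L4IT" = 1.5, "L2/3IT" = 1.2,
                         "L5IT" = 1, "PVALB" = 0.8, "SST" = 0.8,
                         "default" = 1)

default_hazard <- function() hazard_step(c(150, 250, 350, 500),
                                         c(0, 0.05, 0.25, 0.5, 0.8))

#' Ground-truth expression program for the synthetic generator
#'
#' Defines, per gene: a baseline log mean (per 100k UMIs) for every
#' subtype; a negative-binomial dispersion; a phase C hinge slope (log
#' fold-change per repeat unit beyond the onset, positive for C+ genes,
#' negative for C-); and, for the phase D panel, a near-zero baseline rate
#' together with a de-repressed rate that applies once a cell has entered
#' the crisis.  Baselines of the non-panel genes are rescaled per subtype so
#' that expected per-100k expression sums to `total_per_100k`, which keeps
#' simulated library sizes consistent with the per-100k normalization used
#' throughout the analysis.  Phase D panel genes are simulated as Poisson
#' (dispersion `Inf`): they are silent genes whose counts are dominated by
#' sampling noise.
#'
#' @param subtypes Character vector of cell types with distinct baselines.
#' @param n_genes Total number of genes.
#' @param n_cplus,n_cminus Numbers of phase C increasing / decreasing genes.
#' @param n_phased Number of phase D panel genes (59 in the cortical panel).
#' @param cplus_slope,cminus_slope Hinge slopes (log FC per repeat unit).
#' @param derep_rate De-repressed expression rate of phase D genes, UMIs
#'   per 100k.
#' @param phased_baseline Baseline leak rate of phase D genes, per 100k
#'   (must be <= 0.1: these genes are normally silent).
#' @param m,n True hinge onset and cap of the phase C program.
#' @param dispersion_range Range of per-gene NB dispersions (size
#'   parameter) drawn uniformly.
#' @param baseline_meanlog,baseline_sdlog Log-normal law of raw baselines
#'   before per-subtype rescaling.
#' @param n_specific Number of identity genes expressed more highly in
#'   `specific_subtypes` (for identity-erosion studies).
#' @param specific_subtypes Subtypes forming the high-expression group for
#'   the identity genes (default: all subtypes whose name starts with "L",
#'   i.e. the pyramidal layers).
#' @param specific_lfc Natural-log fold difference of identity genes
#'   between the two groups (default `log(8)`).
#' @param cminus_from_specific If `TRUE`, the C- genes are drawn from the
#'   identity-gene pool, coupling phase C decline to cell identity.
#' @param total_per_100k Normalization target for summed baselines.
#' @param seed Optional integer seed.
#' @return A list of class `expression_truth` with elements `genes`
#'   (per-gene table), `baseline` (gene x subtype log per-100k matrix),
#'   `panels` (list of gene sets), `m`, `n`, `subtypes`.
#' @export
expression_truth <- function(subtypes = default_subtypes,
                             n_genes = 300, n_cplus = 30, n_cminus = 30,
                             n_phased = 59,
                             cplus_slope = 0.01, cminus_slope = -0.01,
                             derep_rate = 10, phased_baseline = 0.001,
                             m = 150L, n = 500L,
                             dispersion_range = c(1, 5),
                             baseline_meanlog = log(150),
                             baseline_sdlog = 1.2,
                             n_specific = 0,
                             specific_subtypes = NULL,
                             specific_lfc = log(8),
                             cminus_from_specific = FALSE,
                             total_per_100k = 1e5,
                             seed = NULL) {
  if (phased_baseline > 0.1)
    stop("'phased_baseline' must be <= 0.1 per 100k: phase D genes are silent")
  if (n_cplus + n_cminus + n_phased + n_specific > n_genes)
    stop("gene classes exceed 'n_genes'")
  build <- function() {
    genes <- sprintf("G%04d", seq_len(n_genes))
    class <- rep("null", n_genes)
    pool <- seq_len(n_genes)
    take <- function(k) {
      if (k == 0) return(integer(0))
      idx <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      idx
    }
    i_phased <- take(n_phased)
    class[i_phased] <- "phaseD"
    i_specific <- if (n_specific > 0) take(n_specific) else integer(0)
    i_cminus <- if (cminus_from_specific) {
      if (n_cminus > n_specific)
        stop("cminus_from_specific requires n_specific >= n_cminus")
      i_specific[seq_len(n_cminus)]
    } else take(n_cminus)
    class[i_cminus] <- "cminus"
    i_cplus <- take(n_cplus)
    class[i_cplus] <- "cplus"

    raw <- rnorm(n_genes, baseline_meanlog, baseline_sdlog)
    # identity and phase C genes sit at moderate, well-detected baselines
    # that are a small share of the transcriptome, so their own regulation
    # does not materially move library sizes (no compositional distortion)
    raw[i_specific] <- rnorm(length(i_specific), log(5), 0.3)
    raw[c(i_cminus, i_cplus)] <- rnorm(length(i_cminus) + length(i_cplus),
                                       log(60), 0.2)
    baseline <- matrix(raw, n_genes, length(subtypes),
                       dimnames = list(genes, subtypes))
    if (length(i_specific)) {
      grpA <- if (is.null(specific_subtypes)) grep("^L", subtypes, value = TRUE)
              else specific_subtypes
      if (!length(grpA) || !all(grpA %in% subtypes))
        stop("'specific_subtypes' must name columns of the baseline table")
      baseline[i_specific, grpA] <- baseline[i_specific, grpA] + specific_lfc
    }
    # null genes absorb the normalization so each subtype's expected
    # per-100k expression sums to total_per_100k; effect-class genes keep
    # their programmed rates, which also keeps their transcriptome share
    # small — their regulation must not move library sizes
    fixed <- c(i_phased, i_cminus, i_cplus, i_specific)
    nulls <- setdiff(seq_len(n_genes), fixed)
    for (j in seq_along(subtypes)) {
      fixed_mass <- sum(exp(baseline[setdiff(fixed, i_phased), j]))
      tot <- sum(exp(baseline[nulls, j]))
      baseline[nulls, j] <- baseline[nulls, j] +
        log((total_per_100k - fixed_mass) / tot)
    }
    baseline[i_phased, ] <- log(phased_baseline)

    slope <- rep(0, n_genes)
    slope[i_cplus] <- rep_len(cplus_slope, n_cplus)
    slope[i_cminus] <- rep_len(cminus_slope, n_cminus)
    disp <- runif(n_genes, dispersion_range[1], dispersion_range[2])
    disp[i_phased] <- Inf
    dr <- rep(0, n_genes)
    dr[i_phased] <- rep_len(derep_rate, n_phased)
    structure(list(
      genes = data.frame(gene = genes, class = class, slope = slope,
                         dispersion = disp, derep_rate = dr,
                         baseline_rate = ifelse(class == "phaseD",
                                                phased_baseline, NA_real_),
                         stringsAsFactors = FALSE),
      baseline = baseline,
      panels = list(phaseD = genes[i_phased], cplus = genes[i_cplus],
                    cminus = genes[i_cminus],
                    specific = genes[i_specific]),
      m = as.integer(m), n = as.integer(n), subtypes = subtypes),
      class = "expression_truth")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate a UMI count matrix under the phase C / phase D model
#'
#' Per cell, a target library size is drawn log-normally; per gene, counts
#' are negative-binomial with mean
#' `N/1e5 * exp(baseline + slope * hinge(cag) + donor + region)`.
#' Phase D panel genes instead emit at their leak rate, switching to the
#' de-repressed rate in cells that have entered the crisis.  Recorded
#' `total_umis` are the realized column sums, so the dataset always passes
#' [validate_dataset()].
#'
#' @param cells Data.frame with `cell_id`, `subtype`, `donor` and
#'   optionally `region`.
#' @param lengths Named CAG lengths (disease allele) per cell.
#' @param phase_d_state Named logical vector of crisis states (default:
#'   none entered).
#' @param truth An [expression_truth()] object.
#' @param library_meanlog,library_sdlog Log-normal law of target library
#'   sizes.
#' @param donor_sd,region_sd SDs of i.i.d. normal donor and region effects
#'   on the log scale.
#' @param seed Optional integer seed.
#' @return List with `counts` (sparse gene x cell matrix), `cells` (input
#'   augmented with `total_umis`), `donor_effects`, `region_effects`.
#' @export
simulate_expression <- function(cells, lengths, phase_d_state = NULL,
                                truth, library_meanlog = log(20000),
                                library_sdlog = 0.35,
                                donor_sd = 0.15, region_sd = 0.05,
                                seed = NULL) {
  stopifnot(inherits(truth, "expression_truth"))
  nc <- nrow(cells)
  ids <- as.character(cells$cell_id)
  if (is.null(names(lengths)) || !all(ids %in% names(lengths)))
    stop("'lengths' must be named and cover every cell")
  if (!all(as.character(cells$subtype) %in% truth$subtypes))
    stop("every cell subtype needs a baseline column in 'truth'")
  if (is.null(phase_d_state))
    phase_d_state <- setNames(rep(FALSE, nc), ids)
  run <- function() {
    ng <- nrow(truth$baseline)
    gene_names <- rownames(truth$baseline)
    N <- rlnorm(nc, library_meanlog, library_sdlog)
    donors <- as.character(cells$donor)
    d_lev <- unique(donors)
    d_eff <- setNames(rnorm(length(d_lev), 0, donor_sd), d_lev)
    r_eff_c <- rep(0, nc)
    if (!is.null(cells$region) && region_sd > 0) {
      regions <- as.character(cells$region)
      r_lev <- unique(regions)
      r_eff <- setNames(rnorm(length(r_lev), 0, region_sd), r_lev)
      r_eff_c <- r_eff[regions]
    } else r_eff <- numeric(0)
    h <- hinge(as.numeric(lengths[ids]), truth$m, truth$n)
    cell_log <- log(N / 1e5) + d_eff[donors] + r_eff_c
    logmu <- truth$baseline[, as.character(cells$subtype), drop = FALSE] +
      outer(truth$genes$slope, h)
    mu <- exp(sweep(logmu, 2, cell_log, "+"))
    pd_rows <- truth$genes$class == "phaseD"
    if (any(pd_rows)) {
      state <- as.numeric(phase_d_state[ids])
      rate <- truth$genes$baseline_rate[pd_rows] +
        outer(truth$genes$derep_rate[pd_rows], state)
      mu[pd_rows, ] <- sweep(rate, 2, N / 1e5, "*")
    }
    if (any(!is.finite(mu))) stop("non-finite simulated means")
    cnt <- matrix(0L, ng, nc)
    fin <- is.finite(truth$genes$dispersion)
    if (any(fin))
      cnt[fin, ] <- rnbinom(sum(fin) * nc, mu = mu[fin, , drop = FALSE],
                            size = rep(truth$genes$dispersion[fin], nc))
    if (any(!fin))
      cnt[!fin, ] <- rpois(sum(!fin) * nc, lambda = mu[!fin, , drop = FALSE])
    counts <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
    dimnames(counts) <- list(gene_names, ids)
    out_cells <- cells
    out_cells$total_umis <- as.integer(Matrix::colSums(counts))
    list(counts = counts, cells = out_cells,
         donor_effects = d_eff, region_effects = r_eff)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a village-style case/control composition study
#'
#' Control donors draw cell-type counts multinomially from base
#' proportions; HD donors draw from the same proportions reweighted by
#' per-type survival factors (a factor of 0.5 means half of that type's
#' cells have been lost).  The reference type used downstream (L5IT by
#' default) should carry survival factor 1.
#'
#' @param n_hd,n_control Numbers of donors per group (both must be > 0).
#' @param survival_factors Named vector in (0, 1] per subtype; unlisted
#'   subtypes get 1.
#' @param counts_per_donor Cells sampled per donor (single value or
#'   per-donor).
#' @param base_proportions Named base composition (defaults to a realistic
#'   pyramidal-type mix).
#' @param seed Optional integer seed.
#' @return List with `abundance` (donor x subtype count matrix),
#'   `conditions` (named "HD"/"control" per donor) and `truth` (the
#'   survival factors used).
#' @export
simulate_village_study <- function(n_hd, n_control, survival_factors = NULL,
                                   counts_per_donor = 10000,
                                   base_proportions = NULL, seed = NULL) {
  if (n_hd <= 0 || n_control <= 0)
    stop("need both groups: n_hd and n_control must be positive")
  if (is.null(base_proportions))
    base_proportions <- c("L2/3IT" = 0.30, "L4IT" = 0.15, "L5IT" = 0.20,
                          "L6IT" = 0.12, "L5ET" = 0.03, "L5/6NP" = 0.06,
                          "L6CT" = 0.09, "L6b" = 0.05)
  subtypes <- names(base_proportions)
  sf <- setNames(rep(1, length(subtypes)), subtypes)
  if (!is.null(survival_factors)) {
    if (any(survival_factors <= 0 | survival_factors > 1))
      stop("survival factors must lie in (0, 1]")
    sf[names(survival_factors)] <- survival_factors
  }
  donors <- c(sprintf("HD%02d", seq_len(n_hd)),
              sprintf("C%02d", seq_len(n_control)))
  conditions <- setNames(rep(c("HD", "control"), c(n_hd, n_control)), donors)
  depth <- rep_len(counts_per_donor, length(donors))
  run <- function() {
    hd_prop <- base_proportions * sf
    hd_prop <- hd_prop / sum(hd_prop)
    ab <- t(vapply(seq_along(donors), function(i) {
      p <- if (conditions[i] == "HD") hd_prop else base_proportions
      as.numeric(rmultinom(1, depth[i], p))
    }, numeric(length(subtypes))))
    dimnames(ab) <- list(donors, subtypes)
    list(abundance = ab, conditions = conditions,
         truth = list(survival_factors = sf,
                      base_proportions = base_proportions))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Survival factors coupled to expansion propensity
#'
#' Maps subtype expansion-rate multipliers to survival factors that
#' decrease with expansion propensity, emulating the observed relation
#' between somatic expansion and neuronal loss.  The slowest type keeps
#' survival 1; the fastest drops to `floor`.
#'
#' @param multipliers Named positive vector of subtype rate multipliers.
#' @param floor Survival factor of the fastest-expanding type.
#' @return Named vector of survival factors in `[floor, 1]`.
#' @export
survival_from_multipliers <- function(multipliers, floor = 0.45) {
  lm <- log(multipliers)
  span <- diff(range(lm))
  if (span == 0) return(setNames(rep(1, length(lm)), names(multipliers)))
  setNames(1 - (1 - floor) * (lm - min(lm)) / span, names(multipliers))
}

#' Simulate a complete paired expression / repeat-length dataset
#'
#' Generates a coherent dataset with every feature the analysis stages
#' assume: donors of both conditions across two cortical regions; cells of
#' several molecular types with subtype-specific expansion kinetics;
#' armadillo-shaped repeat-length distributions; phase C hinge expression
#' effects; a discrete phase D crisis; fine cluster labels with imperfect
#' subclass assignments (for taxonomy mapping); and missingness of the CAG
#' measurement.  A ground-truth ledger records everything a recovery test
#' needs.
#'
#' @param n_cells Number of nuclei.
#' @param truth An [expression_truth()] object (default built from
#'   `truth_args`).
#' @param kinetics An [expansion_kinetics()] object (default uses
#'   [default_multipliers] over the pyramidal types).
#' @param hazard Phase D entry hazard (function of CAG length).
#' @param n_hd_donors,n_control_donors Donor counts.
#' @param regions Cortical-area labels.
#' @param age Donor age in years (integration time for expansion).
#' @param inherited_range Range of inherited disease-allele lengths across
#'   HD donors.
#' @param missing_rate Fraction of cells whose CAG measurement is masked.
#' @param clusters_per_subtype Fine clusters nested in each subtype.
#' @param label_purity Probability that a cell's observed subclass label
#'   matches its true subtype.
#' @param subtype_proportions Optional named composition; default uniform
#'   over the truth's subtypes.
#' @param truth_args List of arguments for [expression_truth()] when
#'   `truth` is NULL.
#' @param seed Integer seed (the generator is fully reproducible).
#' @return A list of class `cag_dataset` with `counts`, `cells` and
#'   `truth` (class `sim_truth`).
#' @export
simulate_dataset <- function(n_cells = 2000, truth = NULL, kinetics = NULL,
                             hazard = default_hazard(),
                             n_hd_donors = 3, n_control_donors = 2,
                             regions = c("BA4", "BA32"),
                             age = 60, inherited_range = c(40, 45),
                             missing_rate = 0.5,
                             clusters_per_subtype = 2,
                             label_purity = 0.95,
                             subtype_proportions = NULL,
                             truth_args = list(), seed = 1L) {
  withr::with_seed(seed, {
    if (is.null(truth)) truth <- do.call(expression_truth, truth_args)
    subtypes <- truth$subtypes
    if (is.null(kinetics))
      kinetics <- expansion_kinetics(subtype_multipliers = default_multipliers)
    donors <- c(sprintf("HD%02d", seq_len(n_hd_donors)),
                if (n_control_donors > 0)
                  sprintf("C%02d", seq_len(n_control_donors)))
    condition <- setNames(rep(c("HD", "control"),
                              c(n_hd_donors, n_control_donors)), donors)
    inherited <- setNames(ifelse(condition == "HD",
                                 round(runif(length(donors),
                                             inherited_range[1],
                                             inherited_range[2])), NA),
                          donors)
    props <- if (is.null(subtype_proportions))
      setNames(rep(1 / length(subtypes), length(subtypes)), subtypes)
    else subtype_proportions / sum(subtype_proportions)
    subtype <- sample(names(props), n_cells, replace = TRUE, prob = props)
    cluster_map <- setNames(
      rep(subtypes, each = clusters_per_subtype),
      unlist(lapply(subtypes, function(s)
        paste0(gsub("[^A-Za-z0-9]", "", s), "_c", seq_len(clusters_per_subtype)))))
    cells <- data.frame(
      cell_id = sprintf("cell%06d", seq_len(n_cells)),
      donor = sample(donors, n_cells, replace = TRUE),
      region = sample(regions, n_cells, replace = TRUE),
      supercluster = "Exc",
      subtype = subtype,
      stringsAsFactors = FALSE)
    cells$cluster <- vapply(subtype, function(s) {
      cands <- names(cluster_map)[cluster_map == s]
      cands[sample.int(length(cands), 1)]
    }, character(1))
    flip <- runif(n_cells) > label_purity
    cells$subclass <- subtype
    if (any(flip))
      cells$subclass[flip] <- vapply(which(flip), function(i)
        sample(setdiff(subtypes, subtype[i]), 1), character(1))
    cells$condition <- unname(condition[cells$donor])

    # repeat lengths: only HD donors carry a disease-range allele
    hd <- cells$condition == "HD"
    lengths_true <- setNames(rep(NA_integer_, n_cells), cells$cell_id)
    other_true <- setNames(rep(18L, n_cells), cells$cell_id)
    if (any(hd)) {
      lens <- simulate_repeat_lengths(cells[hd, ], kinetics,
                                      inherited = inherited[condition == "HD"],
                                      age = age)
      lengths_true[lens$cell_id] <- lens$cag_hd
      other_true[lens$cell_id] <- lens$cag_other
    }
    pd_state <- setNames(rep(FALSE, n_cells), cells$cell_id)
    if (any(hd))
      pd_state[hd] <- simulate_phase_d_states(lengths_true[hd], hazard)
    expr_len <- lengths_true
    expr_len[is.na(expr_len)] <- 19L  # control cells: no disease allele
    sim <- simulate_expression(cells, expr_len, pd_state, truth)
    cells <- sim$cells
    cells$inherited_cag_hd <- ifelse(hd, inherited[cells$donor], NA_integer_)
    cells$inherited_cag_other <- 18L
    cells$cag_hd <- unname(lengths_true)
    cells$cag_other <- unname(other_true)
    cells$cag_other[!hd] <- NA_integer_
    measured <- hd & runif(n_cells) >= missing_rate
    cells$cag_hd[!measured] <- NA_integer_
    cells$cag_other[!measured] <- NA_integer_
    cells <- cells[, c("cell_id", "donor", "region", "supercluster",
                       "cluster", "subclass", "subtype", "condition",
                       "total_umis", "cag_hd", "cag_other",
                       "inherited_cag_hd", "inherited_cag_other")]
    truth_ledger <- structure(list(
      kinetics = kinetics, expression = truth,
      lengths = lengths_true, phase_d_state = pd_state,
      cluster_map = cluster_map,
      donor_effects = sim$donor_effects,
      region_effects = sim$region_effects,
      inherited = inherited, seed = seed), class = "sim_truth")
    structure(list(counts = sim$counts, cells = cells, truth = truth_ledger),
              class = "cag_dataset")
  })
}

#' Expected fraction of quiescent-scoring cells among long-repeat cells
#'
#' Closed-form mixture expectation of the generator: given each cell's
#' library size and a flat entry hazard, the probability that its phase D
#' panel score (panel UMIs per 100k) is at most `score_cut`.  Panel counts
#' are Poisson in the generator, so the panel sum is Poisson with mean
#' `rate * N / 1e5`; a score of `score_cut` corresponds to
#' `floor(score_cut * N / 1e5)` raw UMIs.  Used as the analytic oracle for
#' the crisis-bimodality structure.
#'
#' @param total_umis Library sizes of the cells under consideration.
#' @param hazard_prob Flat phase D entry probability for these cells.
#' @param truth An [expression_truth()] object (supplies panel size, leak
#'   and de-repressed rates).
#' @param score_cut Score threshold (default 1 per 100k).
#' @return Expected fraction of cells with score <= `score_cut`.
#' @export
expected_quiescent_fraction <- function(total_umis, hazard_prob, truth,
                                        score_cut = 1) {
  pd <- truth$genes$class == "phaseD"
  lam0 <- sum(truth$genes$baseline_rate[pd])
  lam1 <- sum(truth$genes$baseline_rate[pd] + truth$genes$derep_rate[pd])
  k <- floor(score_cut * total_umis / 1e5)
  mean((1 - hazard_prob) * ppois(k, lam0 * total_umis / 1e5) +
         hazard_prob * ppois(k, lam1 * total_umis / 1e5))
}
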
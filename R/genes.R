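#' Hinge function of CAG-repeat length
#'
#' The hinge covariate of the per-gene models: zero below the onset `m`,
#' then growing one unit per repeat unit until the cap `n`:
#' `0` if `cag < m`, else `min(cag, n) - m`.  With the default onset of
#' 150 units it encodes a phase C program that commences only once a
#' cell's tract passes ~150 CAGs and escalates with further expansion.
#'
#' @param cag CAG-repeat length(s).
#' @param m Onset (default 150).
#' @param n Cap (default 500); must exceed `m`.
#' @return Non-negative numeric vector.
#' @export
#' @examples
#' hinge(c(100, 160, 600))  # 0, 10, 350
hinge <- function(cag, m = 150, n = 500) {
  if (m >= n) stop("hinge parameters must satisfy m < n")
  ifelse(cag < m, 0, pmin(cag, n) - m)
}

#' Per-cell phase D panel score
#'
#' Sum of the UMI counts of the phase D panel genes in each cell,
#' normalized to 100k total UMIs: `sum(panel counts) * 1e5 / N`.
#'
#' @param counts Gene-by-cell count matrix.
#' @param panel Character vector of panel gene symbols (all must be rows
#'   of `counts`).
#' @param total_umis Per-cell total UMI counts (default: column sums).
#' @return Named numeric vector of per-100k scores.
#' @export
phase_d_score <- function(counts, panel, total_umis = NULL) {
  missing_genes <- setdiff(panel, rownames(counts))
  if (length(missing_genes))
    stop("panel gene(s) absent from the count matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  if (is.null(total_umis)) total_umis <- Matrix::colSums(counts)
  if (any(total_umis == 0)) stop("cells with zero total UMIs cannot be scored")
  s <- Matrix::colSums(counts[panel, , drop = FALSE]) * 1e5 / total_umis
  setNames(as.numeric(s), colnames(counts))
}

#' Logistic phase D probability
#'
#' Probability that a cell has entered the phase D crisis, as a logistic
#' function of its panel score: `1 / (1 + exp(-S * (score - M)))`, with
#' steepness `S` and midpoint `M` (per-100k units).  Strictly increasing in
#' the score.
#'
#' @param score Per-100k panel score(s) from [phase_d_score()].
#' @param S Steepness (default 2).
#' @param M Midpoint (default 2 per-100k).
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' phase_d_prob(2)           # 0.5 at the midpoint
#' phase_d_prob(0, S = 2, M = 2)  # 1/(1 + e^4)
phase_d_prob <- function(score, S = 2, M = 2) {
  plogis(S * (score - M))
}

#' Downsample cells for per-gene model fitting
#'
#' Thins the dense mid-range of the repeat-length distribution before the
#' per-gene fits: cells with CAG length in the half-open `interval`
#' (default `(35, 100]`) are kept independently with probability `keep`,
#' while every cell above the interval — the long-repeat cells that drive
#' phase C/D inference — and every cell at or below its lower edge is
#' retained.
#'
#' @param cells Data.frame with a `cag_hd` column, present for every row.
#' @param interval Numeric length-2 half-open interval `(lower, upper]`.
#' @param keep Retention probability inside the interval (default 0.10).
#' @param seed Optional integer seed (fixed seed gives a deterministic
#'   subset).
#' @return The retained rows of `cells`.
#' @export
downsample_for_fitting <- function(cells, interval = c(35, 100),
                                   keep = 0.10, seed = NULL) {
  if (anyNA(cells$cag_hd))
    stop("every cell entering the fit must have a CAG measurement")
  inside <- cells$cag_hd > interval[1] & cells$cag_hd <= interval[2]
  draw <- function() runif(nrow(cells)) < keep
  u <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  cells[!inside | u, , drop = FALSE]
}

#' Specification of the per-gene negative-binomial model
#'
#' Bundles the hinge parameters, the phase D logistic parameters and panel,
#' and the factor covariates of the per-gene model
#' `E_g ~ NB(mu_g, v_g)` with
#' `log(mu_g) = log(N) + f_{m,n}(CAG) + phaseD.prob_{S,M} + donor + region
#' + subcluster` (offset coefficient fixed at 1).
#'
#' @param m,n Hinge onset and cap.
#' @param S,M Phase D logistic steepness and midpoint.
#' @param panel Phase D panel gene symbols; `NULL` omits the phase D
#'   covariate.
#' @param covariates Factor covariates taken from the cell table when
#'   present with >= 2 levels.
#' @return A list of class `gene_model_spec`.
#' @export
gene_model_spec <- function(m = 150, n = 500, S = 2, M = 2, panel = NULL,
                            covariates = c("donor", "region", "subcluster")) {
  if (m >= n) stop("hinge parameters must satisfy m < n")
  if (S <= 0) stop("'S' must be positive")
  structure(list(m = m, n = n, S = S, M = M, panel = panel,
                 covariates = covariates), class = "gene_model_spec")
}

# assemble the per-cell design data shared by all genes
build_gene_design <- function(counts, cells, spec) {
  if (anyNA(cells$cag_hd))
    stop("cells entering per-gene fits must have a CAG measurement")
  idx <- match(cells$cell_id, colnames(counts))
  if (anyNA(idx)) stop("cells absent from the count matrix")
  design <- data.frame(hinge_cov = hinge(cells$cag_hd, spec$m, spec$n))
  score <- NULL
  if (!is.null(spec$panel)) {
    score <- phase_d_score(counts[, idx, drop = FALSE], spec$panel,
                           cells$total_umis)
    design$phased_cov <- phase_d_prob(score, spec$S, spec$M)
  }
  terms <- c("hinge_cov", if (!is.null(spec$panel)) "phased_cov")
  for (f in intersect(spec$covariates, names(cells))) {
    v <- as.character(cells[[f]])
    if (length(unique(v)) >= 2L) {
      design[[f]] <- stats::relevel(factor(v), ref = names(which.max(table(v))))
      terms <- c(terms, f)
    }
  }
  design$log_n <- log(cells$total_umis)
  list(design = design, terms = terms, col_idx = idx, score = score,
       total_umis = cells$total_umis)
}

# when the fitted gene belongs to the phase D panel, its own counts are
# removed from its de-repression covariate (leave-one-out score), so the
# coefficient never regresses a gene on itself
design_for_gene <- function(gene, y, bd, spec) {
  design <- bd$design
  if (!is.null(spec$panel) && gene %in% spec$panel) {
    loo <- bd$score - y * 1e5 / bd$total_umis
    design$phased_cov <- phase_d_prob(loo, spec$S, spec$M)
  }
  design
}

fit_one_gene <- function(y, design, terms) {
  res <- list(beta_hinge = NA_real_, se_hinge = NA_real_, p_hinge = NA_real_,
              beta_phased = NA_real_, se_phased = NA_real_,
              p_phased = NA_real_, dispersion = NA_real_,
              loglik = NA_real_, converged = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + "),
                                 "+ offset(log_n)"))
  dat <- design
  dat$y <- y
  fit <- tryCatch(suppressWarnings(MASS::glm.nb(fml, data = dat)),
                  error = function(e) NULL)
  theta <- if (!is.null(fit)) fit$theta else NA_real_
  if (is.null(fit) || !fit$converged) {
    # NB estimation fails for essentially Poisson genes (dispersion -> Inf),
    # e.g. silent panel genes; fall back to the Poisson limit of the model
    fit <- tryCatch(suppressWarnings(
      stats::glm(fml, data = dat, family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(res)
    theta <- Inf
  }
  sm <- summary(fit)$coefficients
  if ("hinge_cov" %in% rownames(sm)) {
    res$beta_hinge <- sm["hinge_cov", 1]
    res$se_hinge <- sm["hinge_cov", 2]
    res$p_hinge <- sm["hinge_cov", 4]
  }
  if ("phased_cov" %in% rownames(sm)) {
    res$beta_phased <- sm["phased_cov", 1]
    res$se_phased <- sm["phased_cov", 2]
    res$p_phased <- sm["phased_cov", 4]
    if (is.finite(res$se_phased) && res$se_phased > 5) {
      # quasi-separation (a gene silent outside phase D cells) degenerates
      # the Wald SE; use a likelihood-ratio test at the fitted dispersion
      fam <- if (is.finite(theta)) MASS::negative.binomial(theta = theta)
             else stats::poisson()
      fml0 <- stats::as.formula(paste(
        "y ~", paste(setdiff(terms, "phased_cov"), collapse = " + "),
        "+ offset(log_n)"))
      fit0 <- tryCatch(suppressWarnings(stats::glm(fml0, data = dat,
                                                   family = fam)),
                       error = function(e) NULL)
      if (!is.null(fit0)) {
        lr <- 2 * (as.numeric(stats::logLik(fit)) -
                     as.numeric(stats::logLik(fit0)))
        res$p_phased <- stats::pchisq(max(lr, 0), df = 1,
                                      lower.tail = FALSE)
      }
    }
  }
  res$dispersion <- theta
  res$loglik <- as.numeric(stats::logLik(fit))
  res$converged <- TRUE
  res
}

#' Fit the negative-binomial model for one gene
#'
#' Maximum-likelihood NB regression with log link, an offset of `log(N)`
#' (total UMIs), the hinge repeat-length covariate, the logistic phase D
#' covariate (when a panel is supplied) and the factor covariates of the
#' specification.  Wald tests give the hinge and phase D p-values; the
#' per-gene dispersion is estimated by ML.
#'
#' @param gene Gene symbol (a row of `counts`).
#' @param counts Gene-by-cell count matrix.
#' @param cells Cell table (typically after [downsample_for_fitting()]);
#'   needs `cell_id`, `cag_hd`, `total_umis` and the factor covariates.
#' @param spec A [gene_model_spec()].
#' @return One-row data.frame: gene, beta_hinge, se_hinge, p_hinge,
#'   beta_phased, se_phased, p_phased, dispersion, detected_fraction,
#'   n_cells, loglik, converged.
#' @export
fit_gene_nbr <- function(gene, counts, cells, spec = gene_model_spec()) {
  if (!gene %in% rownames(counts)) stop("gene '", gene, "' not in matrix")
  bd <- build_gene_design(counts, cells, spec)
  y <- as.numeric(counts[gene, bd$col_idx])
  res <- if (all(y == 0)) {
    list(beta_hinge = NA_real_, se_hinge = NA_real_, p_hinge = NA_real_,
         beta_phased = NA_real_, se_phased = NA_real_, p_phased = NA_real_,
         dispersion = NA_real_, loglik = NA_real_, converged = FALSE)
  } else fit_one_gene(y, design_for_gene(gene, y, bd, spec), bd$terms)
  data.frame(gene = gene, beta_hinge = res$beta_hinge,
             se_hinge = res$se_hinge, p_hinge = res$p_hinge,
             beta_phased = res$beta_phased, se_phased = res$se_phased,
             p_phased = res$p_phased, dispersion = res$dispersion,
             detected_fraction = mean(y > 0), n_cells = length(y),
             loglik = res$loglik, converged = res$converged,
             stringsAsFactors = FALSE)
}

#' Fit negative-binomial models across genes
#'
#' Runs [fit_gene_nbr()] for every requested gene (all-zero genes are
#' skipped) and appends Benjamini-Hochberg adjusted q-values for the hinge
#' and phase D coefficients, computed separately across all converged
#' fits.  Phase D panel genes are fitted like any other gene, but with
#' their own counts removed from their de-repression covariate
#' (leave-one-out score) so a gene is never regressed on itself.
#'
#' @inheritParams fit_gene_nbr
#' @param genes Genes to fit (default: all rows of `counts`).
#' @param fdr_method Adjustment method for [stats::p.adjust()].
#' @return Data.frame of class `gene_fits`, one row per fitted gene, with
#'   `q_hinge` and `q_phased` columns.
#' @export
fit_gene_models <- function(counts, cells, spec = gene_model_spec(),
                            genes = NULL, fdr_method = "BH") {
  if (is.null(genes)) genes <- rownames(counts)
  bd <- build_gene_design(counts, cells, spec)
  sub <- counts[genes, bd$col_idx, drop = FALSE]
  nonzero <- Matrix::rowSums(sub) > 0
  if (any(!nonzero))
    message(sum(!nonzero), " all-zero gene(s) skipped")
  rows <- lapply(genes[nonzero], function(g) {
    y <- as.numeric(sub[g, ])
    res <- fit_one_gene(y, design_for_gene(g, y, bd, spec), bd$terms)
    data.frame(gene = g, beta_hinge = res$beta_hinge,
               se_hinge = res$se_hinge, p_hinge = res$p_hinge,
               beta_phased = res$beta_phased, se_phased = res$se_phased,
               p_phased = res$p_phased, dispersion = res$dispersion,
               detected_fraction = mean(y > 0),
               n_cells = ncol(sub), loglik = res$loglik,
               converged = res$converged, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  if (is.null(fits)) stop("no fittable genes")
  n_fail <- sum(!fits$converged)
  if (n_fail) message(n_fail, " gene fit(s) did not converge")
  fits$q_hinge <- NA_real_
  fits$q_phased <- NA_real_
  ok <- fits$converged
  fits$q_hinge[ok] <- p.adjust(fits$p_hinge[ok], method = fdr_method)
  fits$q_phased[ok] <- p.adjust(fits$p_phased[ok], method = fdr_method)
  class(fits) <- c("gene_fits", "data.frame")
  fits
}

#' Call phase C and phase D genes from fitted models
#'
#' Phase C genes are those with a significant hinge coefficient (split by
#' sign into C+ and C-); phase D genes must pass a stringent FDR (default
#' 0.1%) and a de-repression fold-change above `fc_d` (default 10), where
#' the fold-change is `exp(beta_phased)` — the fitted change between
#' phase D probability 0 and 1.  Non-converged fits are never called.
#'
#' @param fits A `gene_fits` table from [fit_gene_models()].
#' @param fdr_c FDR threshold for phase C calls.
#' @param fdr_d FDR threshold for phase D calls.
#' @param fc_d Minimum phase D fold-change.
#' @return List with character vectors `cplus`, `cminus`, `phased`.
#' @export
classify_phase_genes <- function(fits, fdr_c = 0.05, fdr_d = 0.001,
                                 fc_d = 10) {
  ok <- fits$converged & !is.na(fits$q_hinge)
  sig_c <- ok & fits$q_hinge < fdr_c
  cplus <- fits$gene[sig_c & fits$beta_hinge > 0]
  cminus <- fits$gene[sig_c & fits$beta_hinge < 0]
  okd <- fits$converged & !is.na(fits$q_phased)
  phased <- fits$gene[okd & fits$q_phased < fdr_d &
                        exp(fits$beta_phased) > fc_d]
  list(cplus = cplus, cminus = cminus, phased = phased)
}

#' Per-cell median fold-change of a gene set
#'
#' Summarizes a phase C gene set as each cell's median fold-change relative
#' to a low-expansion baseline.  Per gene, the baseline is the mean
#' per-100k expression over cells with CAG length in `baseline_interval`
#' (computed within the cell's subtype when a `subtype_col` is present, so
#' type-specific expression does not masquerade as a repeat-length effect);
#' the per-cell fold-change adds a pseudocount to numerator and
#' denominator; the cell's summary is the median over the genes that pass
#' the detection floor (genes detected in fewer than `detected_floor` of
#' the cells are excluded, which suppresses ratio noise from
#' barely-detected genes).
#'
#' @param counts Gene-by-cell count matrix.
#' @param cells Cell table with `cell_id`, `cag_hd`, `total_umis`.
#' @param gene_set Character vector of gene symbols.
#' @param detected_floor Minimum detected fraction (default 0.90).
#' @param baseline_interval Half-open CAG interval defining baseline cells
#'   (default `(0, 100]`).
#' @param pseudocount Per-100k pseudocount (default 1).
#' @param subtype_col Optional column of `cells` giving the subtype within
#'   which baselines are computed.
#' @return Data.frame with `cell_id`, `cag_hd`, `median_fc` and the number
#'   of genes used.
#' @export
median_fc_trajectory <- function(counts, cells, gene_set,
                                 detected_floor = 0.90,
                                 baseline_interval = c(0, 100),
                                 pseudocount = 1, subtype_col = NULL) {
  if (!length(gene_set)) stop("empty gene set")
  if (anyNA(cells$cag_hd)) stop("all cells need a CAG measurement")
  idx <- match(cells$cell_id, colnames(counts))
  sub <- counts[intersect(gene_set, rownames(counts)), idx, drop = FALSE]
  det <- Matrix::rowMeans(sub > 0)
  keep <- det >= detected_floor
  if (!any(keep))
    stop("no gene in the set is detected in at least ",
         round(100 * detected_floor), "% of cells")
  sub <- sub[keep, , drop = FALSE]
  per100k <- Matrix::t(Matrix::t(sub) * (1e5 / cells$total_umis))
  base_cells <- cells$cag_hd > baseline_interval[1] &
    cells$cag_hd <= baseline_interval[2]
  if (!any(base_cells))
    stop("no baseline cells in the interval (", baseline_interval[1], ", ",
         baseline_interval[2], "]")
  groups <- if (!is.null(subtype_col) && subtype_col %in% names(cells))
    as.character(cells[[subtype_col]]) else rep("all", nrow(cells))
  fc <- matrix(NA_real_, nrow(sub), ncol(sub))
  for (g in unique(groups)) {
    in_g <- groups == g
    base_g <- in_g & base_cells
    if (!any(base_g)) base_g <- base_cells  # fall back to the global baseline
    baseline <- Matrix::rowMeans(per100k[, base_g, drop = FALSE])
    fc[, in_g] <- (as.matrix(per100k[, in_g, drop = FALSE]) + pseudocount) /
      (baseline + pseudocount)
  }
  data.frame(cell_id = cells$cell_id, cag_hd = cells$cag_hd,
             median_fc = apply(fc, 2, median),
             n_genes = nrow(sub), stringsAsFactors = FALSE)
}

#' Compare phase C slopes between two contexts
#'
#' Pairs per-gene hinge coefficients fitted in two contexts (e.g.
#' upper-layer vs deep-layer pyramidal neurons, or cortex vs striatum),
#' restricted to genes with strong evidence (`p_hinge < p_cut`) in at
#' least one context, and reports their correlation and sign agreement.
#' Highly concordant slopes indicate a shared phase C program; slopes that
#' scatter around independence indicate distinct programs.
#'
#' @param fits_a,fits_b `gene_fits` tables over a shared gene universe.
#' @param p_cut Evidence threshold (default 1e-10).
#' @return List of class `phase_c_comparison`: `genes` (data.frame with
#'   both slopes), `correlation`, `sign_agreement`, `n_genes`.
#' @export
compare_phase_c <- function(fits_a, fits_b, p_cut = 1e-10) {
  shared <- intersect(fits_a$gene, fits_b$gene)
  if (!length(shared)) stop("disjoint gene universes")
  a <- fits_a[match(shared, fits_a$gene), ]
  b <- fits_b[match(shared, fits_b$gene), ]
  ok <- a$converged & b$converged
  sel <- ok & (pmin(a$p_hinge, b$p_hinge) < p_cut)
  sel[is.na(sel)] <- FALSE
  genes <- data.frame(gene = shared[sel],
                      beta_hinge_a = a$beta_hinge[sel],
                      beta_hinge_b = b$beta_hinge[sel],
                      stringsAsFactors = FALSE)
  correlation <- if (nrow(genes) >= 3)
    cor(genes$beta_hinge_a, genes$beta_hinge_b) else NA_real_
  structure(list(genes = genes, correlation = correlation,
                 sign_agreement = if (nrow(genes))
                   mean(sign(genes$beta_hinge_a) == sign(genes$beta_hinge_b))
                 else NA_real_,
                 n_genes = nrow(genes), p_cut = p_cut),
            class = "phase_c_comparison")
}

#' @export
print.phase_c_comparison <- function(x, ...) {
  cat(sprintf(
    "Phase C cross-context comparison: %d genes at p < %g\n", x$n_genes,
    x$p_cut))
  cat(sprintf("  slope correlation %.3f, sign agreement %.3f\n",
              x$correlation, x$sign_agreement))
  invisible(x)
}

#' Profile-likelihood search for the hinge onset
#'
#' Refits the per-gene models over a grid of candidate onsets `m` and
#' sums the log-likelihood across genes; the maximizing `m` estimates the
#' repeat length at which the phase C program commences (about 150 CAGs).
#'
#' @param counts,cells,spec As in [fit_gene_models()].
#' @param genes Genes whose likelihoods are profiled (typically called
#'   phase C genes).
#' @param m_grid Candidate onsets (default 110 to 200 by 10).
#' @return List with `m_hat` and `profile` (data.frame of m, loglik,
#'   n_converged).
#' @export
profile_hinge_onset <- function(counts, cells, genes,
                                m_grid = seq(110, 200, by = 10),
                                spec = gene_model_spec()) {
  profile <- do.call(rbind, lapply(m_grid, function(m) {
    sp <- spec
    sp$m <- m
    bd <- build_gene_design(counts, cells, sp)
    ll <- vapply(genes, function(g) {
      res <- fit_one_gene(as.numeric(counts[g, bd$col_idx]), bd$design,
                          bd$terms)
      if (res$converged) res$loglik else NA_real_
    }, numeric(1))
    data.frame(m = m, loglik = sum(ll, na.rm = TRUE),
               n_converged = sum(!is.na(ll)))
  }))
  # compare only over m values where the same number of genes converged
  full <- profile$n_converged == max(profile$n_converged)
  best <- profile$m[full][which.max(profile$loglik[full])]
  list(m_hat = best, profile = profile)
}
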
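#' Binary phase D call
#'
#' A cell is called as having entered the phase D de-repression crisis
#' when its logistic entry probability exceeds `prob_cut` (strictly):
#' `phase_d_prob(score, S, M) > prob_cut`.
#'
#' @param score Per-100k panel score(s) from [phase_d_score()].
#' @param S,M Logistic steepness and midpoint.
#' @param prob_cut Probability threshold (default 0.5, i.e. score > M).
#' @return Logical vector.
#' @export
call_phase_d <- function(score, S = 2, M = 2, prob_cut = 0.5) {
  phase_d_prob(score, S, M) > prob_cut
}

#' Fraction of cells in phase D by CAG-length bin
#'
#' Bins cells by repeat length and reports, per half-open bin
#' `(lower, upper]`, the fraction of cells called in phase D with an exact
#' binomial confidence interval, plus quantiles of the score distribution.
#' The expected pattern: entry is rare at 150-250 units and rises with
#' further expansion.
#'
#' @param cells Data.frame with `cell_id` and `cag_hd` (present for all).
#' @param scores Named per-100k scores covering every cell.
#' @param bins Strictly increasing bin edges (default
#'   `c(150, 250, 350, 500, Inf)`).
#' @param S,M,prob_cut Passed to [call_phase_d()].
#' @param conf Confidence level.
#' @param min_cells Bins with fewer cells are flagged `small = TRUE`.
#' @return Data.frame of class `phase_d_summary`: bin, n, fraction, lo,
#'   hi, small, and score quantiles (q25/q50/q75).
#' @export
entry_fraction_by_bin <- function(cells, scores,
                                  bins = c(150, 250, 350, 500, Inf),
                                  S = 2, M = 2, prob_cut = 0.5,
                                  conf = 0.95, min_cells = 20) {
  if (is.unsorted(bins, strictly = TRUE))
    stop("'bins' must be strictly increasing edges (bins cannot overlap)")
  if (anyNA(cells$cag_hd)) stop("every binned cell needs a CAG measurement")
  sc <- scores[cells$cell_id]
  if (anyNA(sc)) stop("every binned cell needs a score")
  entered <- call_phase_d(sc, S, M, prob_cut)
  lab <- findInterval(cells$cag_hd, bins, left.open = TRUE)
  rows <- lapply(seq_len(length(bins) - 1L), function(i) {
    in_bin <- lab == i
    nm <- sprintf("(%g,%g]", bins[i], bins[i + 1])
    n <- sum(in_bin)
    if (n == 0)
      return(data.frame(bin = nm, lower = bins[i], upper = bins[i + 1],
                        n = 0L, fraction = NA_real_, lo = NA_real_,
                        hi = NA_real_, small = TRUE, q25 = NA_real_,
                        q50 = NA_real_, q75 = NA_real_))
    x <- sum(entered[in_bin])
    ci <- binom.test(x, n, conf.level = conf)$conf.int
    q <- quantile(sc[in_bin], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(bin = nm, lower = bins[i], upper = bins[i + 1], n = n,
               fraction = x / n, lo = ci[1], hi = ci[2],
               small = n < min_cells, q25 = q[1], q50 = q[2], q75 = q[3])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phase_d_summary", "data.frame")
  out
}

#' Structure of the phase D crisis among long-repeat cells
#'
#' Restricted to cells with CAG length beyond `threshold_length` (default
#' 150), reports the bimodal crisis structure: (i) the fraction of cells
#' with panel score at most `low_cut` (the quiescent mode — most
#' long-repeat cells still express essentially no phase D transcripts);
#' (ii) among cells with score above `mid_cut`, the fraction with score at
#' least `high_cut` (the crisis mode); and (iii), when counts and the
#' panel are supplied, the per-cell number of distinct panel genes
#' detected.
#'
#' @param cells Data.frame with `cell_id` and `cag_hd`.
#' @param scores Named per-100k scores.
#' @param threshold_length Minimum CAG length (exclusive) for inclusion.
#' @param low_cut,mid_cut,high_cut Score cuts (defaults 1, 2, 10 per-100k).
#' @param counts,panel Optional: count matrix and panel genes for distinct
#'   panel-gene counts.
#' @return List of class `crisis_structure`: `n_cells`,
#'   `fraction_quiescent`, `n_above_mid`, `fraction_high_given_mid`,
#'   `distinct_genes` (named per-cell counts or NULL).
#' @export
crisis_structure <- function(cells, scores, threshold_length = 150,
                             low_cut = 1, mid_cut = 2, high_cut = 10,
                             counts = NULL, panel = NULL) {
  keep <- !is.na(cells$cag_hd) & cells$cag_hd > threshold_length
  if (!any(keep))
    stop("no cells with CAG length > ", threshold_length)
  ids <- cells$cell_id[keep]
  sc <- scores[ids]
  above_mid <- sc > mid_cut
  distinct <- NULL
  if (!is.null(counts) && !is.null(panel))
    distinct <- setNames(
      as.integer(Matrix::colSums(counts[panel, ids, drop = FALSE] > 0)), ids)
  structure(list(
    n_cells = length(ids),
    fraction_quiescent = mean(sc <= low_cut),
    n_above_mid = sum(above_mid),
    fraction_high_given_mid = if (any(above_mid))
      mean(sc[above_mid] >= high_cut) else NA_real_,
    low_cut = low_cut, mid_cut = mid_cut, high_cut = high_cut,
    distinct_genes = distinct), class = "crisis_structure")
}

#' @export
print.crisis_structure <- function(x, ...) {
  cat(sprintf("Phase D crisis structure (%d long-repeat cells)\n", x$n_cells))
  cat(sprintf("  score <= %g (quiescent): %.1f%%\n", x$low_cut,
              100 * x$fraction_quiescent))
  cat(sprintf("  of %d cells with score > %g, %.1f%% have score >= %g\n",
              x$n_above_mid, x$mid_cut,
              100 * x$fraction_high_given_mid, x$high_cut))
  if (!is.null(x$distinct_genes))
    cat(sprintf("  distinct panel genes per cell: max %d\n",
                max(x$distinct_genes)))
  invisible(x)
}

#' Does crisis magnitude track repeat length?
#'
#' Among cells called in phase D, rank-correlates the panel score (crisis
#' magnitude) with CAG length and attaches a seeded permutation p-value.
#' In the data the magnitude does not track length — length predicts
#' whether a cell has entered the crisis, not how far it has progressed.
#'
#' @param cells Data.frame with `cell_id` and `cag_hd`.
#' @param scores Named per-100k scores.
#' @param S,M,prob_cut Passed to [call_phase_d()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed for the permutations.
#' @return List: `status` ("ok" or "insufficient"), `n_entered`, `rho`
#'   (Spearman), `p_perm` (two-sided).
#' @export
magnitude_vs_length <- function(cells, scores, S = 2, M = 2,
                                prob_cut = 0.5, n_perm = 1000,
                                seed = NULL) {
  sc <- scores[cells$cell_id]
  entered <- call_phase_d(sc, S, M, prob_cut) & !is.na(cells$cag_hd)
  n <- sum(entered)
  if (n < 10)
    return(list(status = "insufficient", n_entered = n, rho = NA_real_,
                p_perm = NA_real_))
  x <- cells$cag_hd[entered]
  y <- sc[entered]
  if (sd(y) == 0 || sd(x) == 0)
    return(list(status = "ok", n_entered = n, rho = 0, p_perm = 1))
  rho <- cor(x, y, method = "spearman")
  perm <- function() {
    vapply(seq_len(n_perm), function(i)
      cor(x, sample(y), method = "spearman"), numeric(1))
  }
  null_rho <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())
  p <- (1 + sum(abs(null_rho) >= abs(rho))) / (n_perm + 1)
  list(status = "ok", n_entered = n, rho = rho, p_perm = p)
}
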
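#' Cell-type specificity scores
#'
#' Per-gene mean per-100k expression in two groups of cells (canonically:
#' pyramidal neurons vs cortical interneurons, control donors only) and
#' the pseudocounted log2 ratio.  A large positive `log2_ratio` marks a
#' gene whose expression distinguishes group A from group B — an identity
#' gene of group A.
#'
#' @param counts Gene-by-cell count matrix.
#' @param cells Cell table with `cell_id` and `total_umis`.
#' @param group_a,group_b Logical vectors over the rows of `cells` (both
#'   groups must be non-empty and disjoint).
#' @param pseudocount Per-100k pseudocount (default 1).
#' @return Data.frame: gene, mean_a, mean_b (per-100k), log2_ratio.
#' @export
specificity_scores <- function(counts, cells, group_a, group_b,
                               pseudocount = 1) {
  if (!any(group_a) || !any(group_b)) stop("both groups must be non-empty")
  if (any(group_a & group_b)) stop("groups must be disjoint")
  idx <- match(cells$cell_id, colnames(counts))
  per100k <- Matrix::t(Matrix::t(counts[, idx, drop = FALSE]) *
                         (1e5 / cells$total_umis))
  mean_a <- Matrix::rowMeans(per100k[, group_a, drop = FALSE])
  mean_b <- Matrix::rowMeans(per100k[, group_b, drop = FALSE])
  data.frame(gene = rownames(counts), mean_a = as.numeric(mean_a),
             mean_b = as.numeric(mean_b),
             log2_ratio = log2((mean_a + pseudocount) /
                                 (mean_b + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Identity-erosion enrichment of phase C declining genes
#'
#' Tests whether the phase C down-regulated (C-) genes are
#' disproportionately cell-identity genes: a one-sided rank-sum
#' (Wilcoxon) comparison of the specificity `log2_ratio` between the C-
#' set and the remaining background genes, with the alternative that C-
#' genes are more group-A-specific.  The test is rank-based, so it is
#' invariant to monotone transforms of expression that preserve the
#' ordering of specificity.
#'
#' @param spec_table Output of [specificity_scores()].
#' @param cminus Character vector of C- gene symbols (must be contained in
#'   `background`).
#' @param background Gene universe (default: all genes in `spec_table`).
#' @return List of class `erosion_enrichment`: `status`, `shift`
#'   (Hodges-Lehmann location shift in log2 units), `p_value`,
#'   `n_cminus`, `n_background`, `method`.
#' @export
erosion_enrichment <- function(spec_table, cminus,
                               background = spec_table$gene) {
  if (!all(cminus %in% background))
    stop("'cminus' must be a subset of 'background'")
  if (length(cminus) < 5)
    return(structure(list(status = "insufficient", shift = NA_real_,
                          p_value = NA_real_, n_cminus = length(cminus),
                          n_background = length(background),
                          method = "one-sided Wilcoxon rank-sum"),
                     class = "erosion_enrichment"))
  other <- setdiff(background, cminus)
  lr <- setNames(spec_table$log2_ratio, spec_table$gene)
  if (!length(other))
    return(structure(list(status = "degenerate", shift = 0,
                          p_value = 1, n_cminus = length(cminus),
                          n_background = length(background),
                          method = "one-sided Wilcoxon rank-sum"),
                     class = "erosion_enrichment"))
  wt <- suppressWarnings(wilcox.test(lr[cminus], lr[other],
                                     alternative = "greater",
                                     conf.int = TRUE))
  structure(list(status = "ok", shift = unname(wt$estimate),
                 p_value = wt$p.value, n_cminus = length(cminus),
                 n_background = length(background),
                 method = "one-sided Wilcoxon rank-sum"),
            class = "erosion_enrichment")
}

#' @export
print.erosion_enrichment <- function(x, ...) {
  cat("Identity-erosion enrichment (", x$method, ")\n", sep = "")
  if (x$status != "ok") {
    cat("  status:", x$status, "\n")
  } else {
    cat(sprintf("  %d C- genes vs %d background: shift %.3f log2 units, p = %.3g\n",
                x$n_cminus, x$n_background - x$n_cminus, x$shift, x$p_value))
  }
  invisible(x)
}
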
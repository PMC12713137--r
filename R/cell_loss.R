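#' Reference-normalized relative abundance per donor
#'
#' Normalizes each donor's per-type cell counts by that donor's count of a
#' reference type (L5IT by default — an abundant pyramidal population with
#' modest somatic expansion).  The normalization removes sequencing-depth
#' and dissection differences: it is invariant to scaling any one donor's
#' counts, and more stable across control donors than fractions of all
#' nuclei, whose denominators drift with age-related changes in other
#' populations.  Donors with zero reference-type cells cannot be
#' normalized and are excluded with a message.
#'
#' @param abundance Donor-by-subtype count matrix (donors in rownames).
#' @param reference_subtype Reference column (default "L5IT").
#' @return Matrix of ratios with the reference column identically 1.
#' @export
relative_abundance <- function(abundance, reference_subtype = "L5IT") {
  if (!reference_subtype %in% colnames(abundance))
    stop("reference subtype '", reference_subtype,
         "' absent from the abundance table")
  ref <- abundance[, reference_subtype]
  drop <- ref == 0
  if (any(drop)) {
    message(sum(drop), " donor(s) with zero ", reference_subtype,
            " cells excluded: ",
            paste(rownames(abundance)[drop], collapse = ", "))
    abundance <- abundance[!drop, , drop = FALSE]
    ref <- ref[!drop]
  }
  sweep(abundance, 1, ref, "/")
}

#' Per-type survival ratios in HD
#'
#' For each cell type: the median reference-normalized abundance among HD
#' donors divided by the median among control donors, with a percentile
#' bootstrap interval resampling donors (the sampling unit) within each
#' group.  A ratio of 0.5 means half of that type's cells have been lost
#' in HD.  Types whose control median is zero are withheld.
#'
#' @param rel_abundance Donor-by-subtype ratio matrix from
#'   [relative_abundance()].
#' @param conditions Named "HD"/"control" labels covering every donor row.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @return Data.frame of class `survival_estimates`: subtype, median_hd,
#'   median_control, survival_ratio, lo, hi, n_donors_hd,
#'   n_donors_control.
#' @export
survival_ratios <- function(rel_abundance, conditions, n_boot = 1000,
                            conf = 0.95, seed = NULL) {
  donors <- rownames(rel_abundance)
  if (is.null(donors) || !all(donors %in% names(conditions)))
    stop("'conditions' must be named and cover every donor")
  cond <- conditions[donors]
  hd <- which(cond == "HD")
  ctl <- which(cond == "control")
  if (length(hd) < 3 || length(ctl) < 3)
    stop("need at least 3 donors per group")
  alpha <- (1 - conf) / 2
  run <- function() {
    do.call(rbind, lapply(colnames(rel_abundance), function(st) {
      x_hd <- rel_abundance[hd, st]
      x_ctl <- rel_abundance[ctl, st]
      med_hd <- median(x_hd)
      med_ctl <- median(x_ctl)
      if (med_ctl == 0) {
        message("control median abundance is zero for ", st,
                "; estimate withheld")
        return(data.frame(subtype = st, median_hd = med_hd,
                          median_control = 0, survival_ratio = NA_real_,
                          lo = NA_real_, hi = NA_real_,
                          n_donors_hd = length(hd),
                          n_donors_control = length(ctl)))
      }
      boot <- vapply(seq_len(n_boot), function(b) {
        m_h <- median(sample(x_hd, replace = TRUE))
        m_c <- median(sample(x_ctl, replace = TRUE))
        if (m_c == 0) NA_real_ else m_h / m_c
      }, numeric(1))
      ci <- quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
      data.frame(subtype = st, median_hd = med_hd, median_control = med_ctl,
                 survival_ratio = med_hd / med_ctl, lo = ci[1], hi = ci[2],
                 n_donors_hd = length(hd), n_donors_control = length(ctl),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("survival_estimates", "data.frame")
  out
}

#' Relate per-type survival to expansion propensity
#'
#' Rank correlation between the per-type survival ratio and the
#' exponentiated subtype coefficient of the expansion regression, with a
#' seeded permutation p-value.  The expectation in HD cortex: strongly
#' negative — fast-expanding pyramidal types (L6b, L5/6NP) suffer the most
#' loss.
#'
#' @param survival A `survival_estimates` table (or data.frame with
#'   `subtype` and `survival_ratio`).
#' @param expansion_coefficients Named vector of exponentiated expansion
#'   coefficients (or any expansion-propensity score) per subtype.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List: `status`, `n_subtypes`, `rho` (Spearman), `p_perm`
#'   (two-sided).
#' @export
survival_vs_expansion <- function(survival, expansion_coefficients,
                                  n_perm = 1000, seed = NULL) {
  shared <- intersect(survival$subtype[!is.na(survival$survival_ratio)],
                      names(expansion_coefficients))
  if (length(shared) < 5)
    return(list(status = "insufficient", n_subtypes = length(shared),
                rho = NA_real_, p_perm = NA_real_))
  s <- survival$survival_ratio[match(shared, survival$subtype)]
  e <- expansion_coefficients[shared]
  if (sd(s) == 0 || sd(e) == 0)
    return(list(status = "ok", n_subtypes = length(shared), rho = 0,
                p_perm = 1))
  rho <- cor(s, e, method = "spearman")
  perm <- function() vapply(seq_len(n_perm), function(i)
    cor(s, sample(e), method = "spearman"), numeric(1))
  null_rho <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())
  p <- (1 + sum(abs(null_rho) >= abs(rho))) / (n_perm + 1)
  list(status = "ok", n_subtypes = length(shared), rho = rho, p_perm = p)
}
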
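#' Pipeline configuration
#'
#' Collects the tunable parameters shared by the analysis stages into a
#' single validated list.  All stages take their defaults from here so that
#' one object (or one YAML file, see [read_config()]) describes a run.
#'
#' @param m Integer, hinge onset in CAG repeat units: repeat length has no
#'   effect on gene expression below `m`.  Default 150, the length at which
#'   phase C expression change commences.
#' @param n Integer, hinge cap in repeat units: the hinge covariate stops
#'   growing at `n`.  Must exceed `m`.  Default 500.
#' @param S Positive real, steepness of the phase D logistic covariate
#'   (per normalized UMI).
#' @param M Positive real, midpoint of the phase D logistic covariate, in
#'   panel UMIs per 100k total UMIs.
#' @param downsample_interval Numeric length-2, the half-open CAG interval
#'   `(lower, upper]` thinned before per-gene fitting.  Default `(35, 100]`.
#' @param downsample_keep_fraction Fraction of cells retained inside the
#'   downsampling interval.  Default 0.10 (a 90% downsampling).
#' @param fdr_method Multiple-testing method passed to [stats::p.adjust()].
#' @param fdr_c FDR threshold for calling phase C genes.
#' @param fdr_d FDR threshold for calling phase D genes (default 0.001,
#'   i.e. FDR < 0.1%).
#' @param fc_d Minimum phase D fold-change (de-repressed vs baseline) for
#'   the stringent phase D call.  Default 10.
#' @param detected_floor Fraction of cells in which a gene must be detected
#'   to enter median fold-change summaries.  Default 0.90.
#' @param prob_cut Probability threshold for the binary phase D call.
#' @param min_cells_per_level Minimum observations per factor level kept in
#'   the expansion regression; also the minimum group size reported by
#'   [expansion_summaries()].
#' @param pseudocount Pseudocount, in per-100k units, used in fold-change
#'   and specificity ratios.
#' @param reference_subtype Reference cell type for abundance normalization.
#' @param seed Integer seed used by stages that draw random numbers.
#'
#' @return A list of class `cag_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(m = 150, n = 500)
#' cfg$downsample_interval
pipeline_config <- function(m = 150L, n = 500L, S = 2, M = 2,
                            downsample_interval = c(35, 100),
                            downsample_keep_fraction = 0.10,
                            fdr_method = "BH",
                            fdr_c = 0.05, fdr_d = 0.001, fc_d = 10,
                            detected_floor = 0.90,
                            prob_cut = 0.5,
                            min_cells_per_level = 20L,
                            pseudocount = 1,
                            reference_subtype = "L5IT",
                            seed = 1L) {
  m <- as.integer(m); n <- as.integer(n)
  if (!is.finite(m) || !is.finite(n) || m >= n)
    stop("hinge parameters must satisfy m < n (got m = ", m, ", n = ", n, ")")
  if (S <= 0) stop("'S' (logistic steepness) must be positive")
  if (M <= 0) stop("'M' (logistic midpoint) must be positive")
  if (length(downsample_interval) != 2L ||
      downsample_interval[1] >= downsample_interval[2])
    stop("'downsample_interval' must be (lower, upper] with lower < upper")
  if (downsample_keep_fraction <= 0 || downsample_keep_fraction > 1)
    stop("'downsample_keep_fraction' must be in (0, 1]")
  if (detected_floor < 0 || detected_floor > 1)
    stop("'detected_floor' must be in [0, 1]")
  structure(list(
    m = m, n = n, S = S, M = M,
    downsample_interval = as.numeric(downsample_interval),
    downsample_keep_fraction = downsample_keep_fraction,
    fdr_method = fdr_method, fdr_c = fdr_c, fdr_d = fdr_d, fc_d = fc_d,
    detected_floor = detected_floor, prob_cut = prob_cut,
    min_cells_per_level = as.integer(min_cells_per_level),
    pseudocount = pseudocount,
    reference_subtype = reference_subtype,
    seed = as.integer(seed)
  ), class = "cag_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults; missing keys take the [pipeline_config()] defaults.
#'
#' @param path Path to a flat YAML file of configuration keys.
#' @return A `cag_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  # YAML 1.1 parses the bare keys n/y as booleans; restore them
  names(raw)[names(raw) == "FALSE"] <- "n"
  names(raw)[names(raw) == "TRUE"] <- "y"
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @export
print.cag_config <- function(x, ...) {
  cat("CAG-phases pipeline configuration\n")
  cat(sprintf("  hinge: m = %d, n = %d\n", x$m, x$n))
  cat(sprintf("  phase D logistic: S = %g, M = %g per-100k\n", x$S, x$M))
  cat(sprintf("  downsampling: keep %.0f%% in (%g, %g]\n",
              100 * x$downsample_keep_fraction,
              x$downsample_interval[1], x$downsample_interval[2]))
  cat(sprintf("  calling: FDR C < %g, FDR D < %g, phase D FC > %g (%s)\n",
              x$fdr_c, x$fdr_d, x$fc_d, x$fdr_method))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# stable 32-bit FNV-1a hash of a character scalar, reported as hex;
# used for configuration fingerprints in run manifests
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a double in [0, 2^32)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    hi <- h %/% 65536
    h <- ((h %% 65536) * 16777619 +
            ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint a configuration
#'
#' Hash of the configuration with keys in canonical (sorted) order, so the
#' fingerprint is stable under key reordering in the source YAML.
#'
#' @param config A `cag_config` list.
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  flat <- unclass(config)
  flat <- flat[order(names(flat))]
  fnv1a_hash(paste(names(flat), vapply(flat, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";"))
}
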
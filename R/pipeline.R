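#' Run the full analysis pipeline
#'
#' Orchestrates the stages end-to-end on a simulated dataset (or, when
#' `dataset` is supplied, on user data in the same schema): simulate →
#' taxonomy mapping → expansion regression → per-gene hinge/phase D models
#' → phase D summaries → identity erosion → cell loss.  Every stage writes
#' a TSV (or JSON) table under `out_dir` and is listed in a run manifest.
#' The run is deterministic: one global seed fans out to per-stage seeds
#' drawn once from it, so stages stay reproducible independently of one
#' another.
#'
#' The configuration may be a [pipeline_config()] object or the path to a
#' YAML file; a YAML configuration must state the core model parameters
#' (`m`, `n`, `S`, `M`, `seed`) explicitly.
#'
#' @param config A `cag_config` or path to a YAML configuration.
#' @param out_dir Output directory (created if absent).
#' @param dataset Optional `cag_dataset` (e.g. from [simulate_dataset()]);
#'   by default a demonstration dataset is simulated.
#' @param n_cells,n_genes Size of the simulated demonstration dataset.
#' @param n_hd_donors_village,n_control_donors_village Donors in the
#'   simulated abundance study of the cell-loss stage.
#' @return A list of class `run_manifest` (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, dataset = NULL,
                         n_cells = 2000, n_genes = 300,
                         n_hd_donors_village = 20,
                         n_control_donors_village = 20) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    names(raw)[names(raw) == "FALSE"] <- "n"
    for (key in c("m", "n", "S", "M", "seed"))
      if (is.null(raw[[key]]))
        stop("configuration missing required key: ", key)
    config <- read_config(config)
  }
  stopifnot(inherits(config, "cag_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- withr::with_seed(config$seed,
                                  sample.int(.Machine$integer.max - 1L, 8))
  stages <- list()
  note <- function(name, ...) {
    stages[[length(stages) + 1L]] <<- list(stage = name,
                                           outputs = unname(c(...)))
  }
  out <- function(f) file.path(out_dir, f)
  tsv <- function(x, f) {
    write.table(x, out(f), sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    f
  }

  ## stage 1: data
  if (is.null(dataset)) {
    # gene-class sizes scale with the panel so small demos stay coherent
    n_cm <- min(30L, round(n_genes * 0.1))
    dataset <- simulate_dataset(
      n_cells = n_cells,
      truth_args = list(
        subtypes = c(default_subtypes, "PVALB", "SST"),
        n_genes = n_genes, n_phased = min(59L, round(n_genes * 0.2)),
        n_cplus = n_cm, n_cminus = n_cm,
        n_specific = max(n_cm, round(n_genes * 0.13)),
        cminus_from_specific = TRUE,
        m = config$m, n = config$n),
      seed = stage_seeds[1])
  }
  counts <- dataset$counts
  cells <- dataset$cells
  truth <- dataset$truth
  write_count_matrix(counts, out("counts.mtx"), out("genes.txt"),
                     out("cells.txt"))
  write_cell_metadata(cells[setdiff(names(cells), "subtype")],
                      out("cell_metadata.tsv"))
  panel <- truth$expression$panels$phaseD
  write_gene_panels(list(phaseD = panel), out("gene_panels.tsv"))
  vr <- validate_dataset(counts, cells)
  if (!vr$pass)
    stop("stage 'data' failed: dataset validation reported ",
         vr$n_violations, " violation(s)")
  note("data", "counts.mtx", "genes.txt", "cells.txt", "cell_metadata.tsv",
       "gene_panels.tsv")

  ## stage 2: taxonomy mapping, independently per region
  maps <- lapply(split(cells, cells$region), function(cc)
    map_clusters(build_confusion(cc)))
  map_tab <- do.call(rbind, lapply(names(maps), function(r) {
    e <- maps[[r]]$entries
    if (nrow(e)) cbind(region = r, e) else NULL
  }))
  agreement <- if (length(maps) >= 2)
    compare_maps(maps[[1]], maps[[2]])$agreement else NA_real_
  note("map-taxonomy", tsv(map_tab, "taxonomy_map.tsv"))

  ## stage 3: expansion regression on measured HD cells
  meas <- cells[cells$condition == "HD" & !is.na(cells$cag_hd), ]
  obs <- data.frame(
    phase_a_expansion = phase_a_expansion(meas$cag_hd,
                                          meas$inherited_cag_hd),
    donor = meas$donor, region = meas$region, subcluster = meas$subclass)
  exp_fit <- fit_expansion_nbr(obs, config$min_cells_per_level)
  if (exp_fit$converged)
    note("fit-expansion", tsv(exp_fit$coefficients,
                              "expansion_coefficients.tsv"))
  summ <- expansion_summaries(meas, by = c("subclass", "region"),
                              thresholds = 100, min_cells = 5)
  note("expansion-summaries", tsv(summ, "expansion_summaries.tsv"))

  ## stage 4: per-gene models on the downsampled fitting set
  fit_cells <- downsample_for_fitting(meas, config$downsample_interval,
                                      config$downsample_keep_fraction,
                                      seed = stage_seeds[4])
  spec <- gene_model_spec(m = config$m, n = config$n, S = config$S,
                          M = config$M, panel = panel)
  fits <- fit_gene_models(counts, fit_cells, spec,
                          fdr_method = config$fdr_method)
  sets <- classify_phase_genes(fits, config$fdr_c, config$fdr_d, config$fc_d)
  jsonlite::write_json(sets, out("gene_sets.json"), pretty = TRUE)
  note("fit-genes", tsv(fits, "gene_fits.tsv"), "gene_sets.json")

  ## stage 5: phase D summaries
  scores <- phase_d_score(counts[, meas$cell_id, drop = FALSE], panel,
                          meas$total_umis)
  bins <- entry_fraction_by_bin(meas, scores, S = config$S, M = config$M,
                                prob_cut = config$prob_cut)
  note("phase-d", tsv(as.data.frame(bins), "phase_d_bins.tsv"))
  crisis <- tryCatch(
    crisis_structure(meas, scores, counts = counts, panel = panel),
    error = function(e) NULL)
  if (!is.null(crisis)) {
    jsonlite::write_json(crisis[c("n_cells", "fraction_quiescent",
                                  "n_above_mid", "fraction_high_given_mid")],
                         out("crisis.json"), auto_unbox = TRUE, digits = NA)
    note("crisis", "crisis.json")
  }

  ## stage 6: identity erosion (needs control interneurons)
  ctl <- cells$condition == "control"
  pyr <- ctl & grepl("^L", cells$subclass)
  inter <- ctl & !grepl("^L", cells$subclass)
  if (any(pyr) && any(inter) && length(sets$cminus) >= 5) {
    spec_tab <- specificity_scores(counts, cells, pyr, inter,
                                   config$pseudocount)
    enr <- erosion_enrichment(spec_tab,
                              intersect(sets$cminus, spec_tab$gene))
    jsonlite::write_json(enr[c("status", "shift", "p_value", "n_cminus",
                               "method")],
                         out("identity_enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    note("identity-erosion", tsv(spec_tab, "specificity.tsv"),
         "identity_enrichment.json")
  } else {
    message("identity-erosion stage skipped (no control interneurons or ",
            "too few C- genes)")
  }

  ## stage 7: cell loss from a simulated village composition study
  sf <- survival_from_multipliers(
    truth$kinetics$subtype_multipliers[default_subtypes])
  village <- simulate_village_study(n_hd_donors_village,
                                    n_control_donors_village,
                                    survival_factors = sf,
                                    seed = stage_seeds[7])
  rel <- relative_abundance(village$abundance, config$reference_subtype)
  surv <- survival_ratios(rel, village$conditions, seed = stage_seeds[7])
  note("cell-loss", tsv(as.data.frame(surv), "survival.tsv"))
  assoc <- survival_vs_expansion(
    surv, truth$kinetics$subtype_multipliers[default_subtypes],
    seed = stage_seeds[7])

  manifest <- structure(list(
    config_hash = config_hash(config), seed = config$seed,
    version = as.character(utils::packageVersion("cagphases")),
    timestamp = format(Sys.time(), tz = "UTC"),
    taxonomy_agreement = agreement,
    survival_expansion_rho = assoc$rho,
    stages = stages), class = "run_manifest")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run %s (seed %d, version %s)\n", x$config_hash,
              x$seed, x$version))
  for (s in x$stages)
    cat(sprintf("  %-20s %s\n", s$stage, paste(s$outputs, collapse = ", ")))
  invisible(x)
}
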
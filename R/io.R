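#' Read a sparse gene-by-cell count matrix
#'
#' Reads MatrixMarket counts plus plain-text gene and cell identifier files
#' (one identifier per line), validating that the declared dimensions match
#' and that counts are non-negative integers.
#'
#' @param path_mtx Path to the MatrixMarket (`.mtx`) file, genes in rows.
#' @param path_genes Path to the gene-symbol file (one symbol per line).
#' @param path_cells Path to the cell-identifier file (one id per line).
#' @return A `dgCMatrix` with gene symbols as rownames and cell ids as
#'   colnames.
#' @export
read_count_matrix <- function(path_mtx, path_genes, path_cells) {
  for (p in c(path_mtx, path_genes, path_cells))
    if (!file.exists(p)) stop("file not found: ", p)
  mat <- Matrix::readMM(path_mtx)
  # pattern matrices (written for all-zero inputs) have no numeric slot
  mat <- methods::as(mat * 1, "CsparseMatrix")
  genes <- readLines(path_genes)
  cells <- readLines(path_cells)
  if (nrow(mat) != length(genes))
    stop("count matrix declares ", nrow(mat), " genes but ", length(genes),
         " gene names were supplied")
  if (ncol(mat) != length(cells))
    stop("count matrix declares ", ncol(mat), " cells but ", length(cells),
         " cell ids were supplied")
  vals <- mat@x
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    stop("count matrix entries must be non-negative integers")
  if (anyDuplicated(genes)) stop("duplicate gene symbols in ", path_genes)
  if (anyDuplicated(cells)) stop("duplicate cell ids in ", path_cells)
  dimnames(mat) <- list(genes, cells)
  mat
}

#' Write a sparse count matrix in MatrixMarket form
#'
#' Inverse of [read_count_matrix()]: writes the `.mtx` file and the two
#' identifier files.
#'
#' @param counts Gene-by-cell matrix with dimnames.
#' @param path_mtx,path_genes,path_cells Output paths.
#' @return Invisibly, the three paths.
#' @export
write_count_matrix <- function(counts, path_mtx, path_genes, path_cells) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene rownames and cell colnames")
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), path_mtx)
  writeLines(rownames(counts), path_genes)
  writeLines(colnames(counts), path_cells)
  invisible(c(path_mtx, path_genes, path_cells))
}

cell_metadata_columns <- c(
  "cell_id", "donor", "region", "supercluster", "cluster", "subclass",
  "condition", "total_umis", "cag_hd", "cag_other",
  "inherited_cag_hd", "inherited_cag_other")

validate_cells <- function(cells) {
  missing_cols <- setdiff(c("cell_id", "donor", "condition", "total_umis"),
                          names(cells))
  if (length(missing_cols))
    stop("cell metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id values")
  if (any(is.na(cells$total_umis)) || any(cells$total_umis < 0))
    stop("total_umis must be non-negative and present for every cell")
  bad_cond <- setdiff(unique(as.character(cells$condition)), c("HD", "control"))
  if (length(bad_cond))
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
         " (expected 'HD' or 'control')")
  if (!is.null(cells$cag_hd)) {
    present <- !is.na(cells$cag_hd)
    if (any(cells$cag_hd[present] < 1))
      stop("cag_hd, when measured, must be a positive repeat length")
  }
  if (!is.null(cells$inherited_cag_hd)) {
    hd <- cells$condition == "HD" & !is.na(cells$inherited_cag_hd)
    if (any(cells$inherited_cag_hd[hd] < 36))
      stop("inherited_cag_hd must be >= 36 repeat units for HD donors")
  }
  for (col in intersect(c("donor", "region", "supercluster", "cluster",
                          "condition"), names(cells))) {
    v <- as.character(cells[[col]])
    if (any(!is.na(v) & !nzchar(v))) stop("empty value in column '", col, "'")
  }
  invisible(cells)
}

#' Read per-cell metadata
#'
#' Tab-separated, one row per nucleus.  Missing CAG measurements are encoded
#' as empty fields or `NA` and kept missing (no imputation).  Validation
#' enforces non-negative UMI totals, known condition labels, and
#' disease-range inherited alleles (>= 36 repeat units) for HD donors.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame with one row per cell.
#' @export
read_cell_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cells <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
  for (col in intersect(c("total_umis", "cag_hd", "cag_other",
                          "inherited_cag_hd", "inherited_cag_other"),
                        names(cells)))
    cells[[col]] <- as.integer(cells[[col]])
  validate_cells(cells)
  cells
}

#' Write per-cell metadata
#'
#' @param cells Cell metadata data.frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_cell_metadata <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read or write a gene panel
#'
#' A panel is a named set of gene symbols (e.g. the 59-gene phase D panel,
#' or the phase C increasing/decreasing sets).  The TSV has columns
#' `panel` and `gene`; a file may hold several panels.
#'
#' @param path TSV path.
#' @param name Optional panel name to select; default returns all panels.
#' @return A named list of character vectors (or a single character vector
#'   when `name` is given).
#' @export
read_gene_panels <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("panel", "gene") %in% names(tab)))
    stop("gene panel file needs columns 'panel' and 'gene'")
  panels <- split(tab$gene, tab$panel)
  if (any(!lengths(panels))) stop("empty gene panel")
  if (is.null(name)) return(panels)
  if (!name %in% names(panels)) stop("no panel named '", name, "' in ", path)
  panels[[name]]
}

#' @rdname read_gene_panels
#' @param panels Named list of character vectors of gene symbols.
#' @export
write_gene_panels <- function(panels, path) {
  stopifnot(is.list(panels), !is.null(names(panels)))
  tab <- data.frame(panel = rep(names(panels), lengths(panels)),
                    gene = unlist(panels, use.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validate a count matrix against cell metadata
#'
#' Produces a report rather than an error: the report lists cell-id set
#' mismatches, disagreements between matrix column sums and recorded
#' `total_umis`, and per-field missingness rates.  The dataset passes when
#' no hard violation is present.
#'
#' @param counts Gene-by-cell count matrix.
#' @param cells Cell metadata data.frame.
#' @return A list of class `validation_report` with elements `pass`,
#'   `n_violations`, `violations` (character), and `missingness` (named
#'   fractions).
#' @export
validate_dataset <- function(counts, cells) {
  violations <- character(0)
  ids_m <- colnames(counts)
  ids_c <- cells$cell_id
  only_m <- setdiff(ids_m, ids_c)
  only_c <- setdiff(ids_c, ids_m)
  if (length(only_m))
    violations <- c(violations, sprintf(
      "%d cell id(s) in matrix but not metadata", length(only_m)))
  if (length(only_c))
    violations <- c(violations, sprintf(
      "%d cell id(s) in metadata but not matrix", length(only_c)))
  shared <- intersect(ids_m, ids_c)
  if (length(shared)) {
    csums <- Matrix::colSums(counts[, shared, drop = FALSE])
    recorded <- cells$total_umis[match(shared, cells$cell_id)]
    bad <- which(csums != recorded)
    if (length(bad))
      violations <- c(violations, sprintf(
        "%d cell(s) with column sum != total_umis", length(bad)))
  }
  miss_cols <- intersect(c("cag_hd", "cag_other", "inherited_cag_hd",
                           "inherited_cag_other", "subclass"), names(cells))
  missingness <- vapply(miss_cols, function(col) mean(is.na(cells[[col]])),
                        numeric(1))
  structure(list(pass = length(violations) == 0L,
                 n_violations = length(violations),
                 violations = violations,
                 missingness = missingness,
                 n_cells = nrow(cells), n_genes = nrow(counts)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Dataset validation: %s (%d violation%s; %d genes x %d cells)\n",
              if (x$pass) "PASS" else "FAIL", x$n_violations,
              if (x$n_violations == 1) "" else "s", x$n_genes, x$n_cells))
  for (v in x$violations) cat("  - ", v, "\n", sep = "")
  if (length(x$missingness)) {
    cat("  missingness:\n")
    for (nm in names(x$missingness))
      cat(sprintf("    %s: %.2f\n", nm, x$missingness[[nm]]))
  }
  invisible(x)
}
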
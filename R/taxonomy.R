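#' Cross-tabulate fine cluster labels against subclass assignments
#'
#' Builds the confusion matrix between a fine-grained cluster labeling and
#' an independent subclass assignment for the same cells, the input to the
#' majority-vote mapping of [map_clusters()].
#'
#' @param cells Data.frame with `cluster` and `subclass` columns.
#' @return Integer matrix, clusters in rows, subclasses in columns.
#' @export
build_confusion <- function(cells) {
  if (!all(c("cluster", "subclass") %in% names(cells)))
    stop("'cells' needs 'cluster' and 'subclass' columns")
  keep <- !is.na(cells$cluster) & !is.na(cells$subclass)
  tab <- table(cluster = as.character(cells$cluster[keep]),
               subclass = as.character(cells$subclass[keep]))
  mat <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  mat
}

#' Map clusters to subclasses by majority vote
#'
#' For each cluster with at least `min_cells` cells, assigns the subclass
#' holding the plurality of its cells and records the purity (plurality
#' fraction).  Smaller clusters are left unmapped ("too few cells"), as are
#' exact ties ("tie") — ties are reported, never silently broken.  Mapped
#' clusters whose purity does not exceed `purity_floor` are flagged rather
#' than dropped; downstream stages may exclude them.
#'
#' @param confusion Matrix from [build_confusion()].
#' @param min_cells Minimum cluster size (default 10 cells).
#' @param purity_floor Purity above which a mapping is considered clean
#'   (default 0.60).
#' @return A list of class `cluster_map` with `entries` (data.frame:
#'   cluster, subclass, purity, n_cells, below_floor) and `unmapped`
#'   (data.frame: cluster, reason).
#' @export
map_clusters <- function(confusion, min_cells = 10, purity_floor = 0.60) {
  if (is.null(dim(confusion)))
    stop("'confusion' must be a cluster x subclass matrix")
  entries <- data.frame(cluster = character(0), subclass = character(0),
                        purity = numeric(0), n_cells = integer(0),
                        below_floor = logical(0), stringsAsFactors = FALSE)
  unmapped <- data.frame(cluster = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (cl in rownames(confusion)) {
    counts <- confusion[cl, ]
    n <- sum(counts)
    if (n < min_cells) {
      unmapped <- rbind(unmapped, data.frame(cluster = cl,
                                             reason = "too few cells"))
      next
    }
    top <- max(counts)
    winners <- names(counts)[counts == top]
    if (length(winners) > 1L) {
      unmapped <- rbind(unmapped, data.frame(cluster = cl, reason = "tie"))
      next
    }
    purity <- top / n
    entries <- rbind(entries, data.frame(
      cluster = cl, subclass = winners, purity = purity,
      n_cells = as.integer(n), below_floor = purity <= purity_floor,
      stringsAsFactors = FALSE))
  }
  structure(list(entries = entries, unmapped = unmapped,
                 min_cells = min_cells, purity_floor = purity_floor),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("Cluster-to-subclass map: %d mapped, %d unmapped\n",
              nrow(x$entries), nrow(x$unmapped)))
  if (nrow(x$entries)) {
    flagged <- sum(x$entries$below_floor)
    cat(sprintf("  median purity %.2f; %d below the %.0f%% floor\n",
                median(x$entries$purity), flagged, 100 * x$purity_floor))
  }
  invisible(x)
}

#' Compare two cluster-to-subclass maps
#'
#' Agreement between mappings derived independently (e.g. from two regions
#' sharing a taxonomy): the fraction of shared clusters assigned the same
#' subclass, with the list of disagreements.
#'
#' @param map_a,map_b `cluster_map` objects over overlapping clusters.
#' @return List with `agreement`, `n_shared`, `disagreements` (data.frame).
#' @export
compare_maps <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "cluster_map"), inherits(map_b, "cluster_map"))
  shared <- intersect(map_a$entries$cluster, map_b$entries$cluster)
  if (!length(shared))
    return(list(agreement = NA_real_, n_shared = 0L,
                disagreements = data.frame()))
  a <- map_a$entries$subclass[match(shared, map_a$entries$cluster)]
  b <- map_b$entries$subclass[match(shared, map_b$entries$cluster)]
  dis <- shared[a != b]
  list(agreement = mean(a == b), n_shared = length(shared),
       disagreements = data.frame(cluster = dis,
                                  subclass_a = a[a != b],
                                  subclass_b = b[a != b],
                                  stringsAsFactors = FALSE))
}
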
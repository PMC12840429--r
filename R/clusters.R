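#' Label connected clusters of occupied sites
#'
#' Partitions occupied sites into 4-connected clusters (nearest neighbors,
#' open boundaries) with a union-find engine using path compression and union
#' by size -- the same partition the classic Hoshen-Kopelman raster pass
#' produces. Empty sites are labeled 0; clusters get positive labels.
#'
#' @param x a [lattice_state()] or a logical occupancy matrix.
#' @return An object of class `"cluster_labeling"`: list with `labels`
#'   (integer matrix), `cluster_sizes` (integer vector indexed by label),
#'   `spanning_labels` (labels of clusters touching both the top and bottom
#'   rows, or both the left and right columns) and `n_occupied`.
#' @examples
#' lab <- label_clusters(matrix(TRUE, 3, 3))
#' lab$cluster_sizes # 9: one cluster
#' @export
label_clusters <- function(x) {
  occ <- if (inherits(x, "lattice_state")) x$occupied else x
  if (!is.matrix(occ) || !is.logical(occ))
    stop("`x` must be a lattice_state or a logical matrix")
  labels <- label_clusters_cpp(occ)
  sizes <- tabulate(labels, nbins = max(labels, 0L))
  structure(
    list(labels = labels, cluster_sizes = sizes,
         spanning_labels = .spanning_labels(labels),
         n_occupied = sum(sizes)),
    class = "cluster_labeling"
  )
}

.spanning_labels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  tb <- intersect(labels[1L, ], labels[nr, ])
  lr <- intersect(labels[, 1L], labels[, nc])
  setdiff(union(tb, lr), 0L)
}

#' Does any cluster span the lattice?
#'
#' A configuration spans when one cluster contains sites in both the top and
#' bottom rows, or in both the left and right columns.
#'
#' @param x a [label_clusters()] result, a [lattice_state()] or a logical
#'   occupancy matrix.
#' @return `TRUE` or `FALSE`.
#' @export
spans <- function(x) {
  if (!inherits(x, "cluster_labeling")) x <- label_clusters(x)
  length(x$spanning_labels) > 0L
}

#' Per-configuration cluster statistics
#'
#' @param labeling a [label_clusters()] result.
#' @return A list with `smax` (size of the largest cluster, spanning or not),
#'   `n_clusters` (number of clusters excluding spanning ones), `histogram`
#'   (named integer vector, size -> count over non-spanning clusters) and
#'   `n_occupied`.
#' @export
cluster_statistics <- function(labeling) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  sizes <- labeling$cluster_sizes
  smax <- if (length(sizes)) max(sizes) else 0L
  nonsp <- if (length(labeling$spanning_labels))
    sizes[-labeling$spanning_labels] else sizes
  hist <- if (length(nonsp)) {
    tab <- tabulate(nonsp)
    keep <- which(tab > 0L)
    setNames(tab[keep], keep)
  } else {
    integer(0)
  }
  list(smax = smax, n_clusters = length(nonsp), histogram = hist,
       n_occupied = labeling$n_occupied)
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("cluster_labeling: %d occupied sites in %d clusters, %s\n",
              x$n_occupied, length(x$cluster_sizes),
              if (length(x$spanning_labels)) "spanning" else "not spanning"))
  invisible(x)
}
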
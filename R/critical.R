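#' Locate the red-bond point of one realization
#'
#' Finds `k*`, the number of removals in the last spanning configuration of a
#' trajectory: the configuration with the first `k*` removals applied spans,
#' and with `k* + 1` it does not. Removals only ever cut connectivity, so
#' spanning is monotone along the trajectory and `k*` is unique. The critical
#' threshold is reported at the last spanning configuration (the red-bond
#' site still present), `pc = 1 - k*/L^2`, together with the observables of
#' that configuration.
#'
#' Two engines implement the same contract. `"bisect"` is the two-phase
#' search: a coarse phase removes sites in batches of `coarse_batch` between
#' spanning checks until spanning is lost, then a binary search pins `k*`
#' inside the last batch; every check is a fresh full relabeling of the
#' configuration. `"reverse"` replays the trajectory backwards with an
#' incremental union-find (see [newman_ziff_critical_index()]) and is the
#' fast path for ensembles. The two agree on every trajectory.
#'
#' @param field a [probability_field()].
#' @param trajectory a [sample_removal_order()] result for that field.
#' @param engine `"bisect"` (coarse + binary search over full relabelings)
#'   or `"reverse"` (reverse union-find).
#' @param coarse_batch sites removed between coarse-phase spanning checks;
#'   default `max(1, floor(L^2 / 100))`.
#' @return An object of class `"critical_point_result"`: list with `spec`,
#'   `k_star`, `pc` (occupied fraction at the red-bond point), `smax_norm`
#'   (largest cluster / `L^2`), `n_norm` (non-spanning cluster count /
#'   `L^2`), `histogram` (non-spanning cluster sizes, size -> count) and
#'   `n_sites`.
#' @examples
#' f <- build_field(lattice_spec(21, 1))
#' res <- find_critical_point(f, sample_removal_order(f, seed = 1))
#' res$pc
#' @export
find_critical_point <- function(field, trajectory,
                                engine = c("bisect", "reverse"),
                                coarse_batch = NULL) {
  stopifnot(inherits(field, "probability_field"),
            inherits(trajectory, "removal_trajectory"))
  engine <- match.arg(engine)
  if (!all(dim(field$q) == trajectory$dim))
    stop("field and trajectory dimensions differ")
  k_star <- if (engine == "reverse") {
    newman_ziff_critical_index(trajectory)
  } else {
    .bisect_critical_index(trajectory, coarse_batch)
  }
  .critical_point_result(trajectory, k_star, engine)
}

.nonbreaking_error <- function(trajectory) {
  stop("non-breaking trajectory: spanning persists after every removable site ",
       "is removed (", length(trajectory$excluded),
       " excluded sites with removal probability 0 remain occupied)",
       call. = FALSE)
}

.bisect_critical_index <- function(trajectory, coarse_batch = NULL) {
  n_total <- length(trajectory$order)
  if (n_total == 0L) .nonbreaking_error(trajectory)
  n_cells <- prod(trajectory$dim)
  batch <- as.integer(coarse_batch %||% max(1L, n_cells %/% 100L))
  if (batch < 1L) stop("`coarse_batch` must be >= 1")
  spans_at <- function(k) spans(trajectory_state(trajectory, k)$occupied)

  # coarse phase: batches of removals until spanning is lost
  checkpoints <- unique(c(seq.int(0L, n_total, by = batch)[-1L], n_total))
  k_lo <- 0L
  k_hi <- NA_integer_
  for (k in checkpoints) {
    if (spans_at(k)) k_lo <- k else { k_hi <- k; break }
  }
  if (is.na(k_hi)) .nonbreaking_error(trajectory)

  # fine phase: binary search; invariant spans_at(k_lo) & !spans_at(k_hi)
  while (k_hi - k_lo > 1L) {
    mid <- (k_lo + k_hi) %/% 2L
    if (spans_at(mid)) k_lo <- mid else k_hi <- mid
  }
  k_lo
}

#' Critical removal index by reverse union-find
#'
#' Independent computation of the critical index `k*`: the trajectory is
#' processed in reverse, adding sites back to the never-removed set while an
#' incremental union-find merges clusters and tracks which lattice edges each
#' cluster touches. The first addition that creates a top-bottom or
#' left-right spanning cluster marks the last spanning configuration of the
#' forward removal process.
#'
#' @inheritParams find_critical_point
#' @return Integer `k*`.
#' @export
newman_ziff_critical_index <- function(trajectory) {
  stopifnot(inherits(trajectory, "removal_trajectory"))
  k <- critical_index_cpp(trajectory$order, trajectory$excluded,
                          trajectory$dim[1L], trajectory$dim[2L])
  if (k < 0L) .nonbreaking_error(trajectory)
  k
}

.critical_point_result <- function(trajectory, k_star, engine) {
  n_cells <- prod(trajectory$dim)
  labeling <- label_clusters(trajectory_state(trajectory, k_star)$occupied)
  stats <- cluster_statistics(labeling)
  structure(
    list(spec = trajectory$spec, k_star = as.integer(k_star),
         pc = (n_cells - k_star) / n_cells,
         smax_norm = stats$smax / n_cells,
         n_norm = stats$n_clusters / n_cells,
         histogram = stats$histogram,
         n_sites = n_cells, engine = engine),
    class = "critical_point_result"
  )
}

#' @export
print.critical_point_result <- function(x, ...) {
  cat(sprintf(paste0("critical_point_result: k* = %d, pc = %.4f, ",
                     "Smax/L^2 = %.4f, n/L^2 = %.4f\n"),
              x$k_star, x$pc, x$smax_norm, x$n_norm))
  invisible(x)
}
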
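#' Lattice specification
#'
#' Immutable parameters of one simulation setting: the lattice side `L`, the
#' perimeter removal probability `qp`, and the distance metric that shapes the
#' iso-probability contours of the removal field.
#'
#' The removal gradient is anchored at the unique central site, so `L` must be
#' odd (and at least 3); an even side has no central site and is rejected
#' rather than silently resolved to some convention. The center is at
#' `((L+1)/2, (L+1)/2)` in 1-based `(row, column)` coordinates and the
#' center-to-perimeter distance is `dmax = (L-1)/2` for every metric.
#'
#' @param L odd integer lattice side, `L >= 3`.
#' @param qp removal probability at the lattice perimeter, in `[0, 1]`.
#'   `qp = 1` gives a uniform field (classical inverse percolation); `qp = 0`
#'   gives the steepest gradient, with perimeter sites never removed.
#' @param metric distance metric: `"chebyshev"` (L-infinity, square contours,
#'   the default), `"euclidean"` (circular) or `"manhattan"` (diamond).
#' @return An object of class `"lattice_spec"`: a list with elements `L`,
#'   `qp`, `metric`, `center` (row, col) and `dmax`.
#' @examples
#' spec <- lattice_spec(101, qp = 0.5)
#' spec$dmax # 50
#' @seealso [build_field()], [sample_removal_order()]
#' @export
lattice_spec <- function(L, qp, metric = c("chebyshev", "euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L != round(L))
    stop("`L` must be a single integer")
  L <- as.integer(L)
  if (L < 3L) stop("`L` must be at least 3")
  if (L %% 2L == 0L)
    stop("`L` must be odd: the removal gradient requires a unique central site ",
         "(got L = ", L, ")")
  if (!is.numeric(qp) || length(qp) != 1L || is.na(qp) || qp < 0 || qp > 1)
    stop("`qp` must be a single value in [0, 1]")
  structure(
    list(L = L, qp = as.numeric(qp), metric = metric,
         center = c((L + 1L) %/% 2L, (L + 1L) %/% 2L),
         dmax = (L - 1) / 2),
    class = "lattice_spec"
  )
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("lattice_spec: L = %d, qp = %g, metric = %s, dmax = %g\n",
              x$L, x$qp, x$metric, x$dmax))
  invisible(x)
}

#' Distance of a site from the lattice center
#'
#' Computes the distance from the central site under the spec's metric:
#' Chebyshev `max(|dx|, |dy|)`, Euclidean `sqrt(dx^2 + dy^2)` or Manhattan
#' `|dx| + |dy|`, where `(dx, dy)` is the integer offset from the center.
#'
#' @param site a length-2 vector `(row, col)` or an n-by-2 matrix of 1-based
#'   site coordinates.
#' @param spec a [lattice_spec()].
#' @return Numeric distance(s), `>= 0`, zero only at the center.
#' @examples
#' spec <- lattice_spec(11, 0.3, "euclidean")
#' site_distance(spec$center + c(3, 4), spec) # 5
#' @export
site_distance <- function(site, spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (is.null(dim(site))) site <- matrix(site, ncol = 2L, byrow = TRUE)
  if (ncol(site) != 2L) stop("`site` must have two columns (row, col)")
  if (any(site < 1L) || any(site > spec$L) || any(site != round(site)))
    stop("site coordinates must be integers in [1, L]")
  dx <- abs(site[, 1L] - spec$center[1L])
  dy <- abs(site[, 2L] - spec$center[2L])
  switch(spec$metric,
    chebyshev = pmax(dx, dy),
    euclidean = sqrt(dx^2 + dy^2),
    manhattan = dx + dy
  )
}

#' Removal probability at a given distance from the center
#'
#' The linear removal gradient `q(d, qp) = 1 - (1 - qp) * d / dmax`, clamped
#' to `[0, 1]`. The probability is 1 at the center (`d = 0`) and `qp` at the
#' perimeter distance `dmax = (L-1)/2`. Under the Euclidean and Manhattan
#' metrics corner sites lie beyond `dmax`, where the raw linear form can be
#' negative; clamping keeps the value a probability while the normalization
#' stays `dmax` for every metric.
#'
#' @param d numeric distance(s) from the center, `>= 0`.
#' @param spec a [lattice_spec()].
#' @return Removal probabilities in `[0, 1]`.
#' @examples
#' spec <- lattice_spec(1001, 0.5)
#' removal_probability(c(0, 250, 500), spec) # 1, 0.75, 0.5
#' @export
removal_probability <- function(d, spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  if (!is.numeric(d) || any(is.na(d)) || any(d < 0))
    stop("`d` must be non-negative")
  pmin(pmax(1 - (1 - spec$qp) * d / spec$dmax, 0), 1)
}

#' Build the removal-probability field
#'
#' Evaluates the linear removal gradient at every site of the lattice,
#' producing the per-site removal probability grid `q[i, j]`.
#'
#' @param spec a [lattice_spec()].
#' @return An object of class `"probability_field"`: a list with the `spec`
#'   and the `L x L` numeric matrix `q`.
#' @examples
#' f <- build_field(lattice_spec(5, 0.5))
#' f$q[3, 3] # 1 at the center
#' f$q[1, ]  # outer ring, all 0.5 under the Chebyshev metric
#' @export
build_field <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  off <- abs(seq_len(spec$L) - spec$center[1L])
  d <- switch(spec$metric,
    chebyshev = outer(off, off, pmax),
    euclidean = sqrt(outer(off^2, off^2, "+")),
    manhattan = outer(off, off, "+")
  )
  probability_field(removal_probability(d, spec), spec = spec)
}

#' Construct a probability field from an explicit grid
#'
#' Low-level constructor accepting any rectangular grid of per-site removal
#' probabilities. [build_field()] is the usual entry point; this constructor
#' exists for hand-built fields in tests and for custom geometries.
#'
#' @param q numeric matrix with entries in `[0, 1]`.
#' @param spec optional [lattice_spec()] the grid was built from.
#' @return An object of class `"probability_field"`.
#' @export
probability_field <- function(q, spec = NULL) {
  if (!is.matrix(q) || !is.numeric(q)) stop("`q` must be a numeric matrix")
  if (any(is.na(q)) || any(q < 0) || any(q > 1))
    stop("all entries of `q` must lie in [0, 1]")
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "lattice_spec"))
    if (!all(dim(q) == spec$L)) stop("`q` must be L x L for the given spec")
  }
  structure(list(spec = spec, q = q), class = "probability_field")
}

#' @export
print.probability_field <- function(x, ...) {
  cat(sprintf("probability_field: %d x %d, q in [%g, %g]\n",
              nrow(x$q), ncol(x$q), min(x$q), max(x$q)))
  if (!is.null(x$spec)) print(x$spec)
  invisible(x)
}
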
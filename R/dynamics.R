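#' Lattice occupancy state
#'
#' A snapshot of which sites are occupied. The simulation starts from full
#' occupancy (`p = 1`) and only ever removes sites.
#'
#' @param occupied logical matrix of site occupancy.
#' @param spec optional [lattice_spec()].
#' @return An object of class `"lattice_state"` with elements `occupied`,
#'   `n_occupied` and `spec`.
#' @export
lattice_state <- function(occupied, spec = NULL) {
  if (!is.matrix(occupied) || !is.logical(occupied))
    stop("`occupied` must be a logical matrix")
  if (any(is.na(occupied))) stop("`occupied` must not contain NA")
  structure(list(spec = spec, occupied = occupied,
                 n_occupied = sum(occupied)),
            class = "lattice_state")
}

#' Fully occupied initial state for a spec
#' @param spec a [lattice_spec()].
#' @return A `"lattice_state"` with every site occupied (`p = 1`).
#' @export
full_lattice_state <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  lattice_state(matrix(TRUE, spec$L, spec$L), spec = spec)
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("lattice_state: %d x %d, %d occupied (p = %.4f)\n",
              nrow(x$occupied), ncol(x$occupied), x$n_occupied,
              x$n_occupied / length(x$occupied)))
  invisible(x)
}

#' One rejection step of the removal process
#'
#' The literal removal dynamics: a uniformly chosen occupied site is
#' inspected, a uniform `R` in `[0, 1]` is drawn, and the site is emptied iff
#' `R < q` at that site. Inspected-but-retained sites stay eligible for later
#' inspection. This is the reference sampler; [sample_removal_order()] draws
#' whole trajectories from the identical law in one pass.
#'
#' Uses the current R random number stream; seed with [set.seed()].
#'
#' @param state a [lattice_state()] with at least one occupied site.
#' @param field a [probability_field()] of matching dimensions.
#' @return A list with `state` (updated), `site` (linear column-major index
#'   of the inspected site) and `removed` (logical).
#' @export
rejection_removal_step <- function(state, field) {
  stopifnot(inherits(state, "lattice_state"), inherits(field, "probability_field"))
  if (!all(dim(state$occupied) == dim(field$q)))
    stop("state and field dimensions differ")
  if (state$n_occupied < 1L) stop("no occupied sites left to inspect")
  occ_idx <- which(state$occupied)
  site <- occ_idx[sample.int(length(occ_idx), 1L)]
  removed <- runif(1L) < field$q[site]
  if (removed) {
    state$occupied[site] <- FALSE
    state$n_occupied <- state$n_occupied - 1L
  }
  list(state = state, site = site, removed = removed)
}

#' Sample a complete removal trajectory
#'
#' Draws the full ordered sequence of site removals of one realization.
#' The order is distributed exactly as the sequence of accepted removals of
#' repeated [rejection_removal_step()] calls: successive weighted sampling
#' without replacement with the site removal probabilities as weights. It is
#' realized as an exponential race -- each site with `q > 0` draws an
#' independent `Exp(1)` variate divided by its `q`, and removal order is
#' ascending in these keys -- so a whole trajectory costs one sort instead of
#' an unbounded rejection loop. Sites with `q = 0` (the perimeter at
#' `qp = 0`) are never removed and are reported in `excluded`.
#'
#' @param field a [probability_field()].
#' @param seed optional integer seed; when given, the trajectory is a pure
#'   function of `(field, seed)` and the caller's RNG state is untouched.
#' @return An object of class `"removal_trajectory"`: list with `spec`,
#'   `dim`, `order` (linear column-major site indices in removal order),
#'   `q_order` (removal probability of each ordered site) and `excluded`
#'   (linear indices of never-removed sites).
#' @examples
#' f <- build_field(lattice_spec(5, 1))
#' tr <- sample_removal_order(f, seed = 1)
#' length(tr$order) # 25: with qp = 1 every site is eventually removed
#' @export
sample_removal_order <- function(field, seed = NULL) {
  stopifnot(inherits(field, "probability_field"))
  q <- as.vector(field$q)
  keys <- with_seed(seed, rexp(length(q))) / q # q = 0 -> Inf, never removed
  removable <- sum(q > 0)
  ord <- order(keys)[seq_len(removable)]
  structure(
    list(spec = field$spec, dim = dim(field$q),
         order = as.integer(ord), q_order = q[ord],
         excluded = as.integer(which(q == 0))),
    class = "removal_trajectory"
  )
}

#' @export
print.removal_trajectory <- function(x, ...) {
  cat(sprintf("removal_trajectory: %d x %d grid, %d removals, %d excluded sites\n",
              x$dim[1L], x$dim[2L], length(x$order), length(x$excluded)))
  invisible(x)
}

#' Trajectory as a step table
#'
#' @param trajectory a [sample_removal_order()] result.
#' @return A data frame with columns `step`, `row`, `col`, `q_at_site`.
#' @export
trajectory_table <- function(trajectory) {
  stopifnot(inherits(trajectory, "removal_trajectory"))
  nr <- trajectory$dim[1L]
  idx <- trajectory$order
  data.frame(
    step = seq_along(idx),
    row = ((idx - 1L) %% nr) + 1L,
    col = ((idx - 1L) %/% nr) + 1L,
    q_at_site = trajectory$q_order
  )
}

#' Occupancy state after the first k removals of a trajectory
#'
#' @param trajectory a [sample_removal_order()] result.
#' @param k number of removals applied, `0 <= k <= length(trajectory$order)`.
#' @return A [lattice_state()].
#' @export
trajectory_state <- function(trajectory, k) {
  stopifnot(inherits(trajectory, "removal_trajectory"))
  k <- as.integer(k)
  if (k < 0L || k > length(trajectory$order))
    stop("`k` must be between 0 and the trajectory length")
  occ <- matrix(TRUE, trajectory$dim[1L], trajectory$dim[2L])
  if (k > 0L) occ[trajectory$order[seq_len(k)]] <- FALSE
  lattice_state(occ, spec = trajectory$spec)
}
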
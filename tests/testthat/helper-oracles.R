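# Independent oracles, deliberately naive: breadth-first flood fill for
# cluster labeling, the literal rejection process for trajectories, and a
# linear scan for the critical index.

# BFS flood fill over 4-neighbors; labels in raster order of discovery.
flood_fill_labels <- function(occ) {
  nr <- nrow(occ); nc <- ncol(occ)
  labels <- matrix(0L, nr, nc)
  next_label <- 0L
  for (start in which(occ)) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    labels[start] <- next_label
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      i <- ((cur - 1L) %% nr) + 1L
      j <- ((cur - 1L) %/% nr) + 1L
      for (nb in c(if (i > 1L) cur - 1L, if (i < nr) cur + 1L,
                   if (j > 1L) cur - nr, if (j < nc) cur + nr)) {
        if (occ[nb] && labels[nb] == 0L) {
          labels[nb] <- next_label
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

# Two labelings induce the same partition iff mapping each site's label to
# the smallest site index of its cluster gives identical matrices.
canonical_partition <- function(labels) {
  occ <- labels != 0L
  reps <- vapply(split(which(occ), labels[occ]), min, integer(1))
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[occ] <- reps[as.character(labels[occ])]
  out
}

same_partition <- function(a, b) identical(canonical_partition(a),
                                           canonical_partition(b))

# Full trajectory from the literal rejection process: repeat single-site
# inspections until every positive-probability site is gone.
rejection_trajectory <- function(field) {
  state <- gradperc::lattice_state(matrix(TRUE, nrow(field$q), ncol(field$q)))
  n_target <- sum(field$q > 0)
  order <- integer(0)
  while (length(order) < n_target) {
    step <- gradperc::rejection_removal_step(state, field)
    state <- step$state
    if (step$removed) order <- c(order, step$site)
  }
  order
}

# Wrap an explicit removal order as a trajectory object.
make_trajectory <- function(order, dim, q = NULL) {
  all_sites <- seq_len(prod(dim))
  structure(
    list(spec = NULL, dim = as.integer(dim), order = as.integer(order),
         q_order = if (is.null(q)) rep(1, length(order)) else q[order],
         excluded = setdiff(all_sites, as.integer(order))),
    class = "removal_trajectory"
  )
}

# Linear-scan critical index: relabel from scratch after every removal.
linear_scan_kstar <- function(trajectory) {
  for (k in seq_len(length(trajectory$order))) {
    occ <- gradperc::trajectory_state(trajectory, k)$occupied
    if (!gradperc::spans(occ)) return(k - 1L)
  }
  NA_integer_
}

# Probability of a complete removal order under successive weighted
# sampling without replacement.
order_probability <- function(order, q) {
  remaining <- q
  p <- 1
  for (site in order) {
    p <- p * remaining[site] / sum(remaining)
    remaining[site] <- 0
  }
  p
}
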
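test_that("binary search matches the linear-scan oracle exhaustively at L = 3", {
  f <- build_field(lattice_spec(3, 1))
  for (seed in 1:100) {
    tr <- sample_removal_order(f, seed = seed)
    k_oracle <- linear_scan_kstar(tr)
    expect_equal(find_critical_point(f, tr, engine = "bisect")$k_star, k_oracle)
    expect_equal(newman_ziff_critical_index(tr), k_oracle)
  }
})

test_that("both engines bracket the red-bond point correctly", {
  for (qp in c(0.2, 0.5, 1.0)) {
    f <- build_field(lattice_spec(21, qp))
    for (seed in 1:10) {
      tr <- sample_removal_order(f, seed = seed)
      res <- find_critical_point(f, tr, engine = "bisect")
      expect_equal(newman_ziff_critical_index(tr), res$k_star)
      expect_true(spans(trajectory_state(tr, res$k_star)$occupied))
      expect_false(spans(trajectory_state(tr, res$k_star + 1L)$occupied))
      expect_equal(res$pc, 1 - res$k_star / 21^2)
      expect_lte(res$smax_norm, res$pc)
    }
  }
})

test_that("degenerate single-column lattices keep trivial horizontal spanning", {
  # every site of a 1-wide lattice touches both the left and right columns,
  # so removing the middle site cuts top-bottom connectivity but spanning
  # (either direction) only fails once the column is empty
  f <- probability_field(matrix(1, 3, 1))
  tr <- make_trajectory(c(2L, 1L, 3L), dim = c(3L, 1L))
  for (eng in c("bisect", "reverse"))
    expect_equal(find_critical_point(f, tr, engine = eng)$k_star, 2L)
  expect_equal(linear_scan_kstar(tr), 2L)
})

test_that("a single removal from a full grid never breaks spanning", {
  # with both dimensions >= 2 there is no single-site cut of a full lattice,
  # so k* >= 1 always; the earliest loss (2x2 diagonal pair) is k* = 1
  for (dims in list(c(2L, 2L), c(3L, 3L), c(3L, 5L))) {
    for (idx in seq_len(prod(dims))) {
      occ <- matrix(TRUE, dims[1L], dims[2L])
      occ[idx] <- FALSE
      expect_true(spans(occ))
    }
  }
})

test_that("all 24 removal orders of the 2x2 lattice give the enumerated k*", {
  # after two removals the remaining pair spans iff it shares a row or a
  # column; the diagonal pairs {1,4} and {2,3} (column-major) lose spanning
  # already at the second removal
  f <- probability_field(matrix(1, 2, 2))
  perms <- rbind(
    expand.grid(1:4, 1:4, 1:4, 1:4)
  )
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 4), ]
  for (i in seq_len(nrow(perms))) {
    ord <- as.integer(perms[i, ])
    tr <- make_trajectory(ord, dim = c(2L, 2L))
    pair <- sort(ord[3:4])
    expected <- if (identical(pair, c(1L, 4L)) || identical(pair, c(2L, 3L)))
      1L else 2L
    expect_equal(newman_ziff_critical_index(tr), expected)
    expect_equal(find_critical_point(f, tr, engine = "bisect")$k_star, expected)
    expect_equal(linear_scan_kstar(tr), expected)
  }
})

test_that("non-breaking trajectories raise an error naming the excluded sites", {
  f <- build_field(lattice_spec(5, 0)) # 16 perimeter sites never removed
  tr <- sample_removal_order(f, seed = 1)
  expect_error(find_critical_point(f, tr, engine = "bisect"),
               "non-breaking trajectory.*16 excluded")
  expect_error(find_critical_point(f, tr, engine = "reverse"),
               "non-breaking trajectory.*16 excluded")
})

test_that("coarse batch size does not change the result", {
  f <- build_field(lattice_spec(15, 0.6))
  tr <- sample_removal_order(f, seed = 4)
  k_ref <- newman_ziff_critical_index(tr)
  for (batch in c(1L, 3L, 50L, 1000L))
    expect_equal(find_critical_point(f, tr, engine = "bisect",
                                     coarse_batch = batch)$k_star, k_ref)
})

test_that("observables at the red-bond point match a direct relabeling", {
  f <- build_field(lattice_spec(21, 0.5))
  tr <- sample_removal_order(f, seed = 8)
  res <- find_critical_point(f, tr)
  lab <- label_clusters(trajectory_state(tr, res$k_star)$occupied)
  st <- cluster_statistics(lab)
  expect_equal(res$smax_norm, st$smax / 21^2)
  expect_equal(res$n_norm, st$n_clusters / 21^2)
  expect_equal(res$histogram, st$histogram)
  # exactly one spanning cluster exists at the red-bond configuration
  expect_length(lab$spanning_labels, 1)
})
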
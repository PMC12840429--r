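test_that("lattice_spec validates its inputs", {
  spec <- lattice_spec(1001, 0.5)
  expect_equal(spec$dmax, 500)
  expect_equal(spec$center, c(501L, 501L))
  expect_error(lattice_spec(200, 0.5), "odd")
  expect_error(lattice_spec(1, 0.5), "at least 3")
  expect_error(lattice_spec(101, 1.2), "\\[0, 1\\]")
  expect_error(lattice_spec(101, -0.1), "\\[0, 1\\]")
})

test_that("site_distance implements the three metrics", {
  for (m in c("chebyshev", "euclidean", "manhattan")) {
    spec <- lattice_spec(11, 0.3, m)
    off <- spec$center + c(3, 4)
    expected <- switch(m, chebyshev = 4, euclidean = 5, manhattan = 7)
    expect_equal(site_distance(off, spec), expected)
    expect_equal(site_distance(spec$center, spec), 0)
  }
  spec <- lattice_spec(11, 0.3)
  expect_error(site_distance(c(0, 5), spec), "in \\[1, L\\]")
  expect_error(site_distance(c(5, 12), spec), "in \\[1, L\\]")
})

test_that("removal_probability matches the linear gradient with clamping", {
  # boundary identities: q(0) = 1 and q(dmax) = qp
  for (qp in c(0, 0.275, 0.5, 1)) {
    spec <- lattice_spec(101, qp)
    expect_equal(removal_probability(0, spec), 1)
    expect_equal(removal_probability(spec$dmax, spec), qp)
  }
  # midpoint of the ramp
  spec <- lattice_spec(1001, 0.5)
  expect_equal(removal_probability(250, spec), 0.75)
  # beyond dmax (euclidean corner) the raw value goes negative and is clamped
  spec <- lattice_spec(101, 0.2, "euclidean")
  d_corner <- sqrt(2) * spec$dmax
  raw <- 1 - (1 - 0.2) * d_corner / spec$dmax
  expect_lt(raw, 0)
  expect_equal(raw, 1 - 0.8 * sqrt(2), tolerance = 1e-12)
  expect_equal(removal_probability(d_corner, spec), 0)
  expect_error(removal_probability(-1, spec), "non-negative")
})

test_that("build_field evaluates the gradient on the whole grid", {
  # qp = 1: constant field for every metric
  for (m in c("chebyshev", "euclidean", "manhattan"))
    expect_true(all(build_field(lattice_spec(7, 1, m))$q == 1))
  # L = 5 chebyshev rings: d = 0, 1, 2 -> 1, 0.75, 0.5
  q <- build_field(lattice_spec(5, 0.5))$q
  expect_equal(q[3, 3], 1)
  ring1 <- q[2:4, 2:4]; ring1[2, 2] <- NA
  expect_true(all(ring1 == 0.75, na.rm = TRUE))
  border <- c(q[1, ], q[5, ], q[, 1], q[, 5])
  expect_true(all(border == 0.5))
})

test_that("the field is invariant under the symmetries of the square", {
  for (m in c("chebyshev", "euclidean", "manhattan")) {
    q <- build_field(lattice_spec(7, 0.3, m))$q
    rot90 <- t(q)[, nrow(q):1]
    expect_equal(q, q[nrow(q):1, ])        # horizontal mirror
    expect_equal(q, q[, ncol(q):1])        # vertical mirror
    expect_equal(q, rot90)                 # quarter turn
    expect_equal(q, t(q))                  # diagonal transpose
  }
})

test_that("field bounds, monotonicity along rays and chebyshev linearity hold", {
  for (m in c("chebyshev", "euclidean", "manhattan")) {
    for (qp in c(0, 0.25, 0.7)) {
      f <- build_field(lattice_spec(9, qp, m))
      expect_gte(min(f$q), 0)
      expect_lte(max(f$q), 1)
      ctr <- f$spec$center
      # rays from the center: right, down, and the main diagonal
      rays <- list(f$q[ctr[1], ctr[2]:9], f$q[ctr[1]:9, ctr[2]],
                   diag(f$q)[ctr[1]:9])
      for (ray in rays) expect_true(all(diff(ray) <= 1e-12))
    }
    expect_true(all(build_field(lattice_spec(9, 1, m))$q == 1))
  }
  # chebyshev: minimum is exactly qp; center-row steps are -(1-qp)/dmax
  f <- build_field(lattice_spec(9, 0.25))
  expect_equal(min(f$q), 0.25)
  row <- f$q[f$spec$center[1], f$spec$center[2]:9]
  expect_equal(unique(round(diff(row), 12)),
               round(-(1 - 0.25) / f$spec$dmax, 12))
})

test_that("probability_field rejects invalid grids", {
  expect_error(probability_field(matrix(c(0.5, 1.2), 1)), "\\[0, 1\\]")
  expect_error(probability_field(matrix(0.5, 3, 3), lattice_spec(5, 1)),
               "L x L")
})
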
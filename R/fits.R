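#' Default fitting window for the cluster-size exponent
#'
#' Lower edge 5 (below which lattice discreteness bends the distribution)
#' and upper edge at the 90th percentile of occupied mass `s * N(s)` over
#' non-spanning clusters, excluding the single largest cluster, beyond which
#' the finite-size cutoff dominates.
#'
#' @param histogram named numeric vector, cluster size -> count.
#' @return Numeric `c(s_min, s_max)`.
#' @export
default_tau_range <- function(histogram) {
  s <- as.numeric(names(histogram))
  counts <- as.numeric(histogram)
  o <- order(s)
  s <- s[o]; counts <- counts[o]
  # drop one count at the largest size (the largest single cluster)
  counts[length(counts)] <- counts[length(counts)] - 1
  mass <- s * counts
  total <- sum(mass)
  s_max <- if (total > 0) s[which(cumsum(mass) >= 0.9 * total)[1L]] else max(s)
  c(5, max(s_max, 5 * 4)) # keep at least a couple of factor-2 bins
}

# Log-binned (factor 2) density of a size histogram restricted to a window.
# Bin b covers integer sizes [2^b, 2^(b+1)), truncated to the window;
# density is count per unit size. The bin representative s_mid is the point
# where a power law with exponent tau_ref has its bin-average density, so a
# histogram exactly proportional to s^-tau_ref is recovered without the
# small-s discreteness bias of the plain geometric midpoint.
log_bin_histogram <- function(histogram, fit_range, tau_ref = NULL) {
  s <- as.numeric(names(histogram))
  counts <- as.numeric(histogram)
  keep <- s >= fit_range[1L] & s <= fit_range[2L]
  s <- s[keep]; counts <- counts[keep]
  if (!length(s)) return(data.frame(s_lo = numeric(0), s_hi = numeric(0),
                                    s_mid = numeric(0), count = numeric(0),
                                    density = numeric(0)))
  b <- floor(log2(s))
  agg <- vapply(split(counts, b), sum, numeric(1))
  bb <- as.integer(names(agg))
  lo <- pmax(2^bb, fit_range[1L])
  hi <- pmin(2^(bb + 1) - 1, fit_range[2L])
  width <- hi - lo + 1
  s_mid <- if (is.null(tau_ref) || !is.finite(tau_ref) || tau_ref <= 0) {
    sqrt(lo * hi)
  } else {
    vapply(seq_along(lo), function(i)
      mean(seq.int(lo[i], hi[i])^(-tau_ref))^(-1 / tau_ref), numeric(1))
  }
  data.frame(s_lo = lo, s_hi = hi, s_mid = s_mid,
             count = agg, density = agg / width)
}

#' Estimate the cluster-size power-law exponent tau
#'
#' At the red-bond point the non-spanning cluster-size distribution follows
#' `N(s) ~ s^-tau`. The counts are binned logarithmically (factor-2 bin
#' edges), normalized per unit size within each bin, and the exponent is the
#' negated least-squares slope of `log(density)` versus `log(s)` over the
#' fitting window. Raw per-size counts are too noisy for a stable slope at
#' moderate lattice sizes; log binning is the standard remedy.
#'
#' @param histogram named numeric vector, cluster size -> count (e.g. the
#'   aggregated `histogram` of [run_ensemble()]).
#' @param fit_range numeric `c(s_min, s_max)`; default [default_tau_range()].
#' @return An object of class `"power_law_fit"`: list with `tau`, `tau_se`,
#'   `fit_range`, `n_bins`, `r_squared` and the binned table `bins`.
#' @examples
#' h <- setNames(1e6 * (1:512)^-2, 1:512)
#' estimate_tau(h, fit_range = c(1, 512))$tau # close to 2
#' @export
estimate_tau <- function(histogram, fit_range = NULL) {
  if (!length(histogram)) stop("`histogram` is empty")
  if (is.null(names(histogram)))
    stop("`histogram` must be named by cluster size")
  fit_range <- fit_range %||% default_tau_range(histogram)
  if (length(fit_range) != 2L || fit_range[1L] >= fit_range[2L])
    stop("`fit_range` must be c(s_min, s_max) with s_min < s_max")
  # self-consistent bin representatives: rebin with the current exponent
  # until the fitted slope stabilizes (an exact discrete power law is then
  # recovered exactly)
  tau_ref <- NULL
  fit <- NULL
  bins <- NULL
  for (iter in 1:25) {
    bins <- log_bin_histogram(histogram, fit_range, tau_ref = tau_ref)
    bins <- bins[bins$count > 0, , drop = FALSE]
    if (nrow(bins) < 4L)
      stop("insufficient data: need >= 4 non-empty logarithmic bins in the ",
           "fitting window, got ", nrow(bins))
    fit <- lm(log(density) ~ log(s_mid), data = bins)
    tau_new <- -unname(coef(fit)[2L])
    if (!is.null(tau_ref) && abs(tau_new - tau_ref) < 1e-9) break
    tau_ref <- tau_new
  }
  slope <- unname(coef(fit)[2L])
  structure(
    list(tau = -slope, tau_se = unname(sqrt(diag(vcov(fit)))[2L]),
         fit_range = fit_range, n_bins = nrow(bins),
         r_squared = suppressWarnings(summary(fit))$r.squared, bins = bins),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: tau = %.3f (se %.3f), %d bins over s in [%g, %g], R^2 = %.4f\n",
              x$tau, x$tau_se, x$n_bins, x$fit_range[1L], x$fit_range[2L],
              x$r_squared))
  invisible(x)
}

#' Exponent tau for every qp of a sweep
#'
#' @param sweep a [sweep_qp()] result.
#' @param fit_range optional common fitting window; by default each qp uses
#'   its own [default_tau_range()].
#' @return Data frame with `qp`, `one_minus_qp`, `tau`, `tau_se` (`NA` where
#'   a histogram has too few bins to fit).
#' @export
tau_by_qp <- function(sweep, fit_range = NULL) {
  stopifnot(inherits(sweep, "qp_sweep"))
  qp <- sweep$summary$qp
  fits <- lapply(seq_along(qp), function(i) {
    h <- sweep$histograms[[i]]
    tryCatch(estimate_tau(h, fit_range = fit_range), error = function(e) NULL)
  })
  data.frame(
    qp = qp, one_minus_qp = 1 - qp,
    tau = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$tau,
                 numeric(1)),
    tau_se = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$tau_se,
                    numeric(1))
  )
}

# Accept a qp_sweep or a bare summary data frame.
.sweep_table <- function(table) {
  if (inherits(table, "qp_sweep")) table <- table$summary
  if (!is.data.frame(table) || !all(c("one_minus_qp", "mean_pc") %in% names(table)))
    stop("`table` must be a qp_sweep or a summary data frame with ",
         "one_minus_qp / mean_* columns")
  table
}

#' Quartic polynomial fit of the critical threshold curve
#'
#' Ordinary least squares of `mean_pc` on powers 0..4 of `(1 - qp)`, weighted
#' by inverse squared standard errors when every row carries a positive
#' `se_pc`. The order-zero coefficient `a0` is the fitted threshold in the
#' uniform-removal limit.
#'
#' @param table a [sweep_qp()] result or its summary data frame with at
#'   least 6 distinct `one_minus_qp` points.
#' @return An object of class `"curve_fit"` with `kind = "polynomial4"`,
#'   `coefficients` (`a0`..`a4`), `r_squared`, `reduced_chi_square` (weighted
#'   fits only, residual weighted sum of squares over n - 5), `weighted` and
#'   `n_points`.
#' @export
fit_pc_polynomial <- function(table) {
  tab <- .sweep_table(table)
  x <- tab$one_minus_qp
  y <- tab$mean_pc
  if (length(unique(x)) < 6L)
    stop("need at least 6 distinct (1 - qp) points for a quartic fit")
  w <- NULL
  if (!is.null(tab$se_pc) && all(is.finite(tab$se_pc)) && all(tab$se_pc > 0))
    w <- 1 / tab$se_pc^2
  X <- cbind(1, x, x^2, x^3, x^4)
  if (qr(X)$rank < 5L) stop("rank-deficient design: (1 - qp) values do not ",
                            "identify a quartic")
  fit <- if (is.null(w)) lm(y ~ x + I(x^2) + I(x^3) + I(x^4))
         else lm(y ~ x + I(x^2) + I(x^3) + I(x^4), weights = w)
  sfit <- suppressWarnings(summary(fit))
  cf <- setNames(unname(coef(fit)), paste0("a", 0:4))
  red_chi2 <- if (is.null(w)) NA_real_ else
    sum(w * residuals(fit)^2) / (length(y) - 5L)
  structure(
    list(kind = "polynomial4", coefficients = cf,
         coef_se = setNames(unname(sfit$coefficients[, 2L]), names(cf)),
         r_squared = sfit$r.squared,
         reduced_chi_square = red_chi2, weighted = !is.null(w),
         n_points = length(y)),
    class = "curve_fit"
  )
}

#' Linear fit of the normalized largest-cluster size
#'
#' Ordinary least squares of `mean_smax_norm` on `(1 - qp)`: the size of the
#' largest cluster at the red-bond point falls linearly as the perimeter
#' becomes more protected.
#'
#' @param table a [sweep_qp()] result or its summary data frame with at
#'   least 3 distinct `one_minus_qp` points.
#' @return A `"curve_fit"` with `kind = "linear"`, `coefficients`
#'   (`intercept`, `slope`), `r_squared` and `n_points`.
#' @export
fit_smax_line <- function(table) {
  tab <- .sweep_table(table)
  if (is.null(tab$mean_smax_norm)) stop("`table` lacks mean_smax_norm")
  x <- tab$one_minus_qp
  y <- tab$mean_smax_norm
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct (1 - qp) points for a linear fit")
  fit <- lm(y ~ x)
  sfit <- suppressWarnings(summary(fit))
  cf <- setNames(unname(coef(fit)), c("intercept", "slope"))
  structure(
    list(kind = "linear", coefficients = cf,
         coef_se = setNames(unname(sfit$coefficients[, 2L]), names(cf)),
         r_squared = sfit$r.squared,
         reduced_chi_square = NA_real_, weighted = FALSE,
         n_points = length(y)),
    class = "curve_fit"
  )
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("curve_fit (%s, %s): R^2 = %.4f over %d points\n", x$kind,
              if (x$weighted) "weighted" else "unweighted",
              x$r_squared, x$n_points))
  print(round(x$coefficients, 6))
  invisible(x)
}
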
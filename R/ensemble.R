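# Deterministic per-realization seed derivation: a sweep is a pure function
# of (L, metric, qp grid, N, base_seed). Kept well below 2^31.
derive_seed <- function(base_seed, qp_index, realization) {
  as.integer((as.numeric(base_seed) + 1000003 * qp_index + realization) %%
               2147483629)
}

#' Simulate one realization to its red-bond point
#'
#' Convenience wrapper: samples a removal trajectory for the field and
#' locates its critical point.
#'
#' @param field a [probability_field()].
#' @param seed integer seed for the realization.
#' @param engine critical-search engine, see [find_critical_point()].
#' @return A `"critical_point_result"`.
#' @export
simulate_realization <- function(field, seed, engine = "reverse") {
  find_critical_point(field, sample_removal_order(field, seed = seed),
                      engine = engine)
}

#' Monte-Carlo ensemble at a single qp
#'
#' Runs `N` independent realizations with deterministically derived seeds
#' `derive(base_seed, qp_index, r)`, locates the red-bond point of each and
#' averages the critical observables. Realizations whose trajectory never
#' loses spanning (possible at `qp = 0`) are recorded and excluded from the
#' averages, never retried.
#'
#' @param spec a [lattice_spec()].
#' @param N number of realizations, `>= 1`.
#' @param base_seed integer base seed.
#' @param qp_index integer offset folded into seed derivation so each row of
#'   a sweep gets its own substream; 0 for standalone ensembles.
#' @param engine critical-search engine, see [find_critical_point()].
#' @return An object of class `"ensemble_result"`: list with `summary` (a
#'   one-row data frame: `qp`, `one_minus_qp`, `N`, `n_used`, `n_failed`,
#'   `mean_pc`, `se_pc`, `mean_smax_norm`, `se_smax_norm`, `mean_n_norm`,
#'   `se_n_norm`), `realizations` (per-realization data frame), and
#'   `histogram` (aggregated non-spanning cluster-size counts, size -> count).
#'   Standard errors are sample SD / sqrt(n); 0 when `n_used` is 1.
#' @examples
#' ens <- run_ensemble(lattice_spec(41, 1), N = 10, base_seed = 7)
#' ens$summary$mean_pc
#' @export
run_ensemble <- function(spec, N, base_seed, qp_index = 0L, engine = "reverse") {
  stopifnot(inherits(spec, "lattice_spec"))
  N <- as.integer(N)
  if (N < 1L) stop("`N` must be at least 1")
  field <- build_field(spec)
  seeds <- vapply(seq_len(N), function(r) derive_seed(base_seed, qp_index, r),
                  integer(1))
  pc <- smax <- nn <- rep(NA_real_, N)
  k_star <- rep(NA_integer_, N)
  hists <- vector("list", N)
  failed <- logical(N)
  for (r in seq_len(N)) {
    res <- tryCatch(simulate_realization(field, seeds[r], engine = engine),
                    error = function(e) {
                      if (grepl("non-breaking trajectory", conditionMessage(e)))
                        NULL else stop(e)
                    })
    if (is.null(res)) { failed[r] <- TRUE; next }
    pc[r] <- res$pc; smax[r] <- res$smax_norm; nn[r] <- res$n_norm
    k_star[r] <- res$k_star
    hists[[r]] <- res$histogram
  }
  if (all(failed))
    stop("all ", N, " realizations were non-breaking (spanning never lost); ",
         "is qp = 0?")
  ok <- !failed
  se <- function(x) if (sum(ok) > 1L) sd(x[ok]) / sqrt(sum(ok)) else 0
  summary <- data.frame(
    qp = spec$qp, one_minus_qp = 1 - spec$qp,
    N = N, n_used = sum(ok), n_failed = sum(failed),
    mean_pc = mean(pc[ok]), se_pc = se(pc),
    mean_smax_norm = mean(smax[ok]), se_smax_norm = se(smax),
    mean_n_norm = mean(nn[ok]), se_n_norm = se(nn)
  )
  structure(
    list(summary = summary,
         realizations = data.frame(seed = seeds, qp = spec$qp, L = spec$L,
                                   k_star = k_star, pc = pc,
                                   smax_norm = smax, n_norm = nn,
                                   failed = failed),
         histogram = merge_histograms(hists[ok]),
         spec = spec),
    class = "ensemble_result"
  )
}

# Sum named size -> count vectors into one aggregated histogram.
merge_histograms <- function(hists) {
  hists <- Filter(function(h) length(h) > 0L, hists)
  if (!length(hists)) return(integer(0))
  sizes <- unlist(lapply(hists, function(h) as.integer(names(h))),
                  use.names = FALSE)
  counts <- unlist(hists, use.names = FALSE)
  tab <- vapply(split(as.numeric(counts), sizes), sum, numeric(1))
  tab <- tab[order(as.integer(names(tab)))]
  setNames(as.integer(tab), names(tab))
}

#' Sweep the perimeter parameter qp
#'
#' Runs one [run_ensemble()] per qp value and assembles the tidy summary
#' table and the per-qp aggregated cluster-size histograms. The whole sweep
#' is a pure function of `(L, metric, qp_values, N, base_seed)`.
#'
#' The default grid is `1 - qp` in `{0, 0.1, ..., 0.9, 0.99}`, covering the
#' full range from uniform removal (`qp = 1`) to a near-protected perimeter
#' (`qp = 0.01`). `qp = 0` risks a perimeter ring that never breaks and is
#' only accepted with `allow_qp0 = TRUE`.
#'
#' @param L odd lattice side.
#' @param metric distance metric, see [lattice_spec()].
#' @param qp_values removal probabilities at the perimeter, each in `(0, 1]`
#'   (or `[0, 1]` with `allow_qp0`).
#' @param N realizations per qp value.
#' @param base_seed integer base seed.
#' @param allow_qp0 accept `qp = 0` despite the non-breaking risk.
#' @param engine critical-search engine.
#' @return An object of class `"qp_sweep"`: list with `summary` (one row per
#'   qp, sorted by `one_minus_qp` ascending), `histograms` (named by qp), and
#'   the sweep parameters.
#' @examples
#' sw <- sweep_qp(L = 21, qp_values = c(1, 0.5), N = 5, base_seed = 1)
#' sw$summary[, c("one_minus_qp", "mean_pc")]
#' @export
sweep_qp <- function(L, metric = "chebyshev",
                     qp_values = 1 - c(seq(0, 0.9, by = 0.1), 0.99),
                     N = 200L, base_seed = 1L, allow_qp0 = FALSE,
                     engine = "reverse") {
  if (!length(qp_values)) stop("`qp_values` must be non-empty")
  if (any(qp_values < 0 | qp_values > 1))
    stop("each qp must lie in [0, 1]")
  if (any(qp_values == 0) && !allow_qp0)
    stop("qp = 0 may never lose spanning (the perimeter ring is never ",
         "removed); pass allow_qp0 = TRUE to run it anyway")
  qp_values <- qp_values[order(1 - qp_values)]
  rows <- vector("list", length(qp_values))
  hists <- vector("list", length(qp_values))
  for (iq in seq_along(qp_values)) {
    ens <- run_ensemble(lattice_spec(L, qp_values[iq], metric), N = N,
                        base_seed = base_seed, qp_index = iq, engine = engine)
    rows[[iq]] <- ens$summary
    hists[[iq]] <- ens$histogram
  }
  names(hists) <- vapply(qp_values, format, character(1), trim = TRUE)
  structure(
    list(summary = do.call(rbind, rows), histograms = hists,
         L = as.integer(L), metric = metric, N = as.integer(N),
         base_seed = as.integer(base_seed)),
    class = "qp_sweep"
  )
}

#' @export
print.qp_sweep <- function(x, ...) {
  cat(sprintf("qp_sweep: L = %d, metric = %s, N = %d per point\n",
              x$L, x$metric, x$N))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
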
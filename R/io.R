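#' Write a matrix as a plain-text grid
#'
#' One lattice row per line, space-separated values.
#'
#' @param m a matrix.
#' @param path output file.
#' @export
write_matrix_txt <- function(m, path) {
  stopifnot(is.matrix(m))
  writeLines(apply(m, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Write a grayscale image as plain (ASCII) PGM
#'
#' Plain-text `P2` format so images stay diffable and portable. Values must
#' already be integers in `[0, maxval]`; matrix rows become image rows.
#'
#' @param values integer matrix of pixel values.
#' @param path output file.
#' @param maxval maximum gray value (default 255).
#' @export
write_pgm <- function(values, path, maxval = 255L) {
  stopifnot(is.matrix(values))
  v <- round(values)
  if (any(v < 0 | v > maxval)) stop("pixel values outside [0, maxval]")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), as.character(maxval)), con)
  writeLines(apply(v, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Render a probability field as a PGM image
#'
#' Pixel value `round(255 * (1 - q))`: dark where removal is unlikely (sites
#' tend to remain), light near the center where `q` approaches 1 -- so the
#' image shows the iso-probability contours of the metric (squares, circles
#' or diamonds).
#'
#' @param field a [probability_field()].
#' @param path output file.
#' @export
write_field_pgm <- function(field, path) {
  stopifnot(inherits(field, "probability_field"))
  write_pgm(round(255 * (1 - field$q)), path)
}

#' Render an occupancy grid as a PGM image
#'
#' Occupied sites black (0), empty sites white (255).
#'
#' @param x a [lattice_state()] or logical matrix.
#' @param path output file.
#' @export
write_occupancy_pgm <- function(x, path) {
  occ <- if (inherits(x, "lattice_state")) x$occupied else x
  stopifnot(is.matrix(occ), is.logical(occ))
  write_pgm(matrix(ifelse(occ, 0L, 255L), nrow(occ)), path)
}

#' Export a removal trajectory as CSV
#'
#' Columns `step`, `row`, `col`, `q_at_site`.
#'
#' @param trajectory a [sample_removal_order()] result.
#' @param path output file.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(trajectory_table(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Export an aggregated cluster-size histogram as long-format CSV
#'
#' Columns `s`, `count`.
#'
#' @param histogram named vector, size -> count.
#' @param path output file.
#' @export
write_histogram_csv <- function(histogram, path) {
  write.csv(data.frame(s = as.integer(names(histogram)),
                       count = as.numeric(histogram)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a histogram CSV back into a named vector
#' @param path a file written by [write_histogram_csv()].
#' @return Named numeric vector, size -> count.
#' @export
read_histogram_csv <- function(path) {
  d <- read.csv(path)
  setNames(d$count, d$s)
}

#' Export a sweep summary as CSV
#' @param sweep a [sweep_qp()] result or its summary data frame.
#' @param path output file.
#' @export
write_summary_csv <- function(sweep, path) {
  tab <- if (inherits(sweep, "qp_sweep")) sweep$summary else sweep
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a sweep summary CSV
#' @param path a file written by [write_summary_csv()].
#' @return The summary data frame.
#' @export
read_summary_csv <- function(path) read.csv(path)

#' Export a fit as JSON
#'
#' @param fit a `"power_law_fit"` or `"curve_fit"` (or a named list of them).
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  strip <- function(f) {
    if (inherits(f, "power_law_fit"))
      list(kind = "power_law", tau = f$tau, tau_se = f$tau_se,
           fit_range = f$fit_range, n_bins = f$n_bins,
           r_squared = f$r_squared)
    else if (inherits(f, "curve_fit"))
      list(kind = f$kind, coefficients = as.list(f$coefficients),
           r_squared = f$r_squared,
           reduced_chi_square = f$reduced_chi_square,
           weighted = f$weighted, n_points = f$n_points)
    else f
  }
  out <- if (inherits(fit, c("power_law_fit", "curve_fit"))) strip(fit)
         else lapply(fit, strip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a provenance record for an output directory
#'
#' Serializes the run configuration, seeds and package version so any output
#' directory can be regenerated exactly.
#'
#' @param config named list of run parameters.
#' @param path output file.
#' @export
write_provenance_json <- function(config, path) {
  config$package <- "gradperc"
  config$package_version <- as.character(packageVersion("gradperc"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
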
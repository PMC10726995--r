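#' Log-spaced diameter grids for DLS spectra
#'
#' DLS size-intensity spectra are histograms over hydrodynamic diameter, binned
#' on a logarithmic axis. A `dls_grid` records the bin edges and centers (in
#' nm) shared by a set of comparable spectra. [dls_grid()] builds a geometric
#' (log-spaced) grid; [grid_from_centers()] reconstructs a grid from the bin
#' centers of an imported spectrum, which may be irregular.
#'
#' The default grid — 70 geometric bins spanning 0.4 to 10,000 nm — emulates
#' the reporting range of a benchtop Zetasizer-class instrument, which covers
#' everything from sub-virion fragments (tens of nm) to large aggregates
#' (500–8,000 nm).
#'
#' @param d_min,d_max Smallest and largest bin edge, nm. Both must be positive
#'   with `d_min < d_max`.
#' @param n_bins Number of bins (at least 2).
#' @return A `dls_grid`: list with `centers` (length `n_bins`, geometric means
#'   of adjacent edges), `edges` (length `n_bins + 1`), `n_bins`, and
#'   `log_spaced` (TRUE when the edge ratio is constant to 1e-9 relative).
#' @examples
#' g <- dls_grid(1, 100, 2)
#' g$edges   # 1, 10, 100
#' g$centers # sqrt(10), sqrt(1000)
#' @export
dls_grid <- function(d_min = 0.4, d_max = 10000, n_bins = 70) {
  if (!is.numeric(d_min) || !is.numeric(d_max) || length(d_min) != 1 ||
      length(d_max) != 1 || !is.finite(d_min) || !is.finite(d_max) ||
      d_min <= 0 || d_min >= d_max) {
    abort("`d_min` and `d_max` must satisfy 0 < d_min < d_max.")
  }
  if (!is.numeric(n_bins) || length(n_bins) != 1 || n_bins < 2 ||
      n_bins != round(n_bins)) {
    abort("`n_bins` must be an integer >= 2.")
  }
  n_bins <- as.integer(n_bins)
  edges <- 10^seq(log10(d_min), log10(d_max), length.out = n_bins + 1L)
  centers <- sqrt(edges[-1L] * edges[-(n_bins + 1L)])
  structure(
    list(centers = centers, edges = edges, n_bins = n_bins, log_spaced = TRUE),
    class = "dls_grid"
  )
}

#' @rdname dls_grid
#' @param centers Strictly increasing, positive bin centers in nm (length
#'   >= 2). Edges are placed at the geometric midpoints of adjacent centers
#'   and extrapolated geometrically at the ends.
#' @export
grid_from_centers <- function(centers) {
  centers <- as.numeric(centers)
  if (length(centers) < 2 || any(!is.finite(centers)) || any(centers <= 0) ||
      any(diff(centers) <= 0)) {
    abort("`centers` must be >= 2 strictly increasing positive diameters (nm).")
  }
  n <- length(centers)
  inner <- sqrt(centers[-1L] * centers[-n])
  lo <- centers[1L]^2 / inner[1L]
  hi <- centers[n]^2 / inner[n - 1L]
  edges <- c(lo, inner, hi)
  ratios <- edges[-1L] / edges[-length(edges)]
  log_spaced <- diff(range(ratios)) <= 1e-9 * mean(ratios)
  structure(
    list(centers = centers, edges = edges, n_bins = n, log_spaced = log_spaced),
    class = "dls_grid"
  )
}

#' @export
print.dls_grid <- function(x, ...) {
  cat(sprintf(
    "<dls_grid> %d bins, %.4g-%.4g nm (%s)\n",
    x$n_bins, x$edges[1L], x$edges[length(x$edges)],
    if (x$log_spaced) "log-spaced" else "irregular"
  ))
  invisible(x)
}

# log10 bin widths, used when intensities are treated as densities per unit
# log10(diameter)
grid_log_widths <- function(grid) {
  diff(log10(grid$edges))
}

is_dls_grid <- function(x) inherits(x, "dls_grid")
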
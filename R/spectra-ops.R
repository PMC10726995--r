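#' Normalize spectra to total area 100
#'
#' Every DLS size-intensity spectrum in this package is compared on the
#' convention that its bin intensities sum to 100 (relative intensity %).
#' Normalization is idempotent and scale-invariant: `normalize(c * x)` equals
#' `normalize(x)` for any `c > 0`.
#'
#' @param spectra Spectra tibble (`sample`, `size_nm`, `intensity`); may hold
#'   several samples, each normalized independently.
#' @return The same tibble with each sample's intensities scaled to sum 100.
#' @export
normalize_spectra <- function(spectra) {
  validate_spectra(spectra)
  totals <- tapply(spectra$intensity, spectra$sample, sum)
  if (any(totals <= 0)) {
    abort(sprintf("degenerate spectrum (all-zero intensity): %s",
                  paste(names(totals)[totals <= 0], collapse = ", ")))
  }
  spectra %>%
    group_by(.data$sample) %>%
    mutate(intensity = .data$intensity * 100 / sum(.data$intensity)) %>%
    ungroup()
}

.normalize_vec <- function(x) {
  s <- sum(x)
  if (s <= 0) abort("degenerate spectrum (all-zero intensity)")
  x * 100 / s
}

#' Resample spectra onto a common size grid
#'
#' Bin-wise spectrum comparisons (see [auc_delta()]) require a shared binning.
#' Intensities are interpreted as densities per unit log10(diameter):
#' each bin value is divided by its source bin's log10 width, the density is
#' interpolated linearly in log10-size at the target bin centers (zero outside
#' the source support), multiplied by the target bin log-widths, and
#' renormalized to area 100. Resampling onto a spectrum's own grid is the
#' identity, and area is conserved for any overlapping target grid.
#'
#' @param spectra Spectra tibble; each sample is resampled independently and
#'   must have at least 2 bins.
#' @param grid Target [dls_grid()].
#' @return Spectra tibble on the target grid's centers, each sample area 100.
#' @export
resample_spectra <- function(spectra, grid) {
  validate_spectra(spectra)
  if (!is_dls_grid(grid)) abort("`grid` must be a dls_grid.")
  spectra %>%
    group_by(.data$sample) %>%
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$size_nm), , drop = FALSE]
      if (nrow(df) < 2) abort("resampling needs spectra with >= 2 bins")
      out <- .resample_vec(df$size_nm, df$intensity, grid)
      tibble(size_nm = grid$centers, intensity = out)
    }) %>%
    ungroup() %>%
    select(all_of(c("sample", "size_nm", "intensity")))
}

.resample_vec <- function(src_centers, src_intensity, grid) {
  src_grid <- grid_from_centers(src_centers)
  dens <- src_intensity / grid_log_widths(src_grid)
  at <- approx(
    x = log10(src_centers), y = dens, xout = log10(grid$centers),
    method = "linear", rule = 1
  )$y
  at[is.na(at)] <- 0 # zero outside the source support
  out <- at * grid_log_widths(grid)
  if (sum(out) <= 0) {
    abort("no overlap between spectrum support and target grid")
  }
  .normalize_vec(out)
}

#' Average replicate spectra
#'
#' Replicate DLS measurements (typically n = 3) are combined by normalizing
#' each to area 100, resampling onto a common grid when bin centers differ,
#' taking the per-bin arithmetic mean, and renormalizing. The result is
#' invariant to the order of the replicates.
#'
#' @param spectra Spectra tibble; every sample present is treated as one
#'   replicate.
#' @param label Sample name for the averaged spectrum (default `"mean"`).
#' @param grid Optional target [dls_grid()]; when NULL, replicates sharing
#'   identical bin centers are averaged in place, otherwise a 70-bin log grid
#'   spanning the union of supports is used.
#' @return One-sample spectra tibble with area 100.
#' @export
average_replicates <- function(spectra, label = "mean", grid = NULL) {
  validate_spectra(spectra)
  spectra <- normalize_spectra(spectra)
  split_int <- split(spectra$intensity, spectra$sample)
  split_size <- split(spectra$size_nm, spectra$sample)
  if (length(split_int) == 0) abort("no spectra to average")

  same_grid <- length(unique(lapply(split_size, function(s) {
    round(sort(log10(s)), 12)
  }))) == 1
  if (is.null(grid) && same_grid) {
    centers <- sort(split_size[[1L]])
    mats <- vapply(names(split_int), function(s) {
      o <- order(split_size[[s]])
      split_int[[s]][o]
    }, numeric(length(centers)))
  } else {
    if (is.null(grid)) grid <- default_union_grid(spectra$size_nm)
    centers <- grid$centers
    mats <- vapply(names(split_int), function(s) {
      o <- order(split_size[[s]])
      .resample_vec(split_size[[s]][o], split_int[[s]][o], grid)
    }, numeric(length(centers)))
  }
  avg <- .normalize_vec(rowMeans(as.matrix(mats)))
  tibble(sample = label, size_nm = centers, intensity = avg)
}

# default shared binning: 70 geometric bins spanning the union of supports
default_union_grid <- function(sizes, n_bins = 70) {
  dls_grid(min(sizes) * 0.999, max(sizes) * 1.001, n_bins)
}

#' Hydrodynamic diameter from the Stokes-Einstein relation
#'
#' Converts a translational diffusion coefficient measured by DLS into a
#' hydrodynamic diameter: `D_H = k_B * T / (3 * pi * eta * D)`, with
#' `k_B = 1.380649e-23` J/K, returned in nm. Defaults correspond to water at
#' 25 degrees C, the standard Zetasizer measurement condition.
#'
#' @param diffusion_coeff Diffusion coefficient, m^2/s.
#' @param temperature Absolute temperature, K (default 298.15).
#' @param viscosity Dynamic viscosity, Pa s (default 8.90e-4, water at 25 C).
#' @return Hydrodynamic diameter(s) in nm. Vectorized over all arguments.
#' @examples
#' stokes_einstein_diameter(4.904e-12, 298.15, 8.872e-4) # ~100.4 nm
#' @export
stokes_einstein_diameter <- function(diffusion_coeff, temperature = 298.15,
                                     viscosity = 8.90e-4) {
  if (any(!is.finite(diffusion_coeff)) || any(diffusion_coeff <= 0) ||
      any(!is.finite(temperature)) || any(temperature <= 0) ||
      any(!is.finite(viscosity)) || any(viscosity <= 0)) {
    abort("All arguments must be finite and positive.")
  }
  d_m <- .kB * temperature / (3 * pi * viscosity * diffusion_coeff)
  d_m * 1e9
}

#' Summarize a spectrum relative to an intact-particle size window
#'
#' Reports the modal diameter and how the spectrum's area splits around a
#' window of expected intact-virion sizes — useful for flagging sub-virion
#' fragments (below) and aggregates (above). Bins are assigned to the three
#' regions by their centers, so fractions are quantized at bin resolution.
#'
#' @param spectra Spectra tibble (may hold several samples).
#' @param intact_window Length-2 numeric `(lo, hi)` in nm; must lie inside the
#'   spectrum's size span.
#' @return Tibble with one row per sample: `sample`, `mode_nm` (center of the
#'   max-intensity bin), `fraction_below`, `fraction_in`, `fraction_above`
#'   (percent of area; they sum to 100).
#' @export
peak_summary <- function(spectra, intact_window) {
  validate_spectra(spectra)
  if (length(intact_window) != 2 || any(!is.finite(intact_window)) ||
      intact_window[1L] <= 0 || intact_window[1L] >= intact_window[2L]) {
    abort("`intact_window` must be (lo, hi) with 0 < lo < hi (nm).")
  }
  spectra <- normalize_spectra(spectra)
  span <- range(spectra$size_nm)
  if (intact_window[1L] < span[1L] || intact_window[2L] > span[2L]) {
    abort(sprintf(
      "window (%g, %g) nm lies outside the grid span (%g, %g) nm",
      intact_window[1L], intact_window[2L], span[1L], span[2L]
    ))
  }
  spectra %>%
    group_by(.data$sample) %>%
    summarise(
      mode_nm = .data$size_nm[which.max(.data$intensity)],
      fraction_below = sum(.data$intensity[.data$size_nm < intact_window[1L]]),
      fraction_in = sum(.data$intensity[.data$size_nm >= intact_window[1L] &
                                          .data$size_nm <= intact_window[2L]]),
      fraction_above = sum(.data$intensity[.data$size_nm > intact_window[2L]]),
      .groups = "drop"
    )
}
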
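#' AUC-delta: L1 divergence between two DLS size spectra
#'
#' The core statistic of the package. Both spectra are normalized to area 100,
#' brought onto a common log-diameter grid, and the sum of the absolute
#' bin-wise intensity differences is taken:
#' \deqn{\mathrm{AUC\Delta} = \sum_i |a_i - b_i|.}
#' Because each spectrum has area 100, the value ranges from 0 (identical
#' spectra) to 200 (entirely non-overlapping spectra). It is symmetric in its
#' arguments and satisfies the triangle inequality on a shared grid.
#'
#' When the two spectra already share bin centers they are compared directly;
#' otherwise both are resampled (see [resample_spectra()]) onto `grid`, which
#' defaults to a 70-bin log grid spanning the union of their supports.
#' Floating-point excursions above 200 are clamped.
#'
#' @param a,b Spectra tibbles, each containing exactly one sample (average
#'   replicates first; see [average_replicates()]).
#' @param grid Optional [dls_grid()] forcing the comparison binning.
#' @return A length-1 numeric of class `"auc_delta"` carrying `a_label`,
#'   `b_label` and `grid` attributes.
#' @examples
#' g <- dls_grid(10, 1000, 3)
#' a <- tibble::tibble(sample = "a", size_nm = g$centers, intensity = c(100, 0, 0))
#' b <- tibble::tibble(sample = "b", size_nm = g$centers, intensity = c(0, 0, 100))
#' auc_delta(a, b) # 200: disjoint spectra
#' auc_delta(a, a) # 0: identical spectra
#' @export
auc_delta <- function(a, b, grid = NULL) {
  a <- single_spectrum(a, "a")
  b <- single_spectrum(b, "b")
  ai <- .normalize_vec(a$intensity)
  bi <- .normalize_vec(b$intensity)

  same <- nrow(a) == nrow(b) && isTRUE(all.equal(a$size_nm, b$size_nm,
                                                 tolerance = 1e-12))
  if (same && is.null(grid)) {
    grid_used <- grid_from_centers(a$size_nm)
  } else {
    grid_used <- if (is.null(grid)) {
      default_union_grid(c(a$size_nm, b$size_nm))
    } else {
      grid
    }
    ai <- .resample_vec(a$size_nm, ai, grid_used)
    bi <- .resample_vec(b$size_nm, bi, grid_used)
  }
  value <- min(sum(abs(ai - bi)), 200)
  structure(value,
            class = c("auc_delta", "numeric"),
            a_label = a$sample[1L], b_label = b$sample[1L], grid = grid_used)
}

#' @export
print.auc_delta <- function(x, ...) {
  cat(sprintf("AUC-delta(%s, %s) = %.4g  [0 = identical, 200 = disjoint]\n",
              attr(x, "a_label"), attr(x, "b_label"), as.numeric(x)))
  invisible(x)
}

# fast path for co-gridded intensity vectors already normalized to area 100
.auc_delta_vec <- function(ai, bi) {
  min(sum(abs(ai - bi)), 200)
}

#' AUC-delta of every sample against a named baseline
#'
#' Convenience table for screening a batch of spectra against a reference
#' spectrum, the shape produced by the `compare` command.
#'
#' @param spectra Spectra tibble with >= 2 samples.
#' @param baseline Sample label of the reference spectrum.
#' @param grid Optional common [dls_grid()].
#' @return Tibble (`sample`, `auc_delta`), baseline excluded, input order
#'   preserved.
#' @export
auc_delta_table <- function(spectra, baseline, grid = NULL) {
  validate_spectra(spectra)
  ids <- unique(spectra$sample)
  if (!baseline %in% ids) {
    abort(sprintf("Baseline '%s' not found. Available samples: %s",
                  baseline, paste(ids, collapse = ", ")))
  }
  base <- spectra %>% filter(.data$sample == baseline)
  others <- setdiff(ids, baseline)
  tibble(
    sample = others,
    auc_delta = purrr::map_dbl(others, function(s) {
      as.numeric(auc_delta(spectra %>% filter(.data$sample == s), base,
                           grid = grid))
    })
  )
}

#' Divergence from baseline across a time or perturbation series
#'
#' Tracks AUC-delta against the averaged baseline measurement for each phage:
#' baseline replicates are averaged once, then each timepoint's replicates are
#' averaged and compared against it. The replicate-level spread (SD of
#' individual replicate-vs-averaged-baseline AUC-delta values) is reported
#' alongside the point value.
#'
#' @param spectra Long spectra tibble with columns `phage_id`, `timepoint`,
#'   `replicate`, `size_nm`, `intensity` (`replicate` optional; a single
#'   replicate is assumed when absent).
#' @param baseline_timepoint Timepoint value identifying the baseline
#'   (default: the smallest timepoint present). Must exist for every phage.
#' @param grid Optional common [dls_grid()].
#' @return Tibble (`phage_id`, `timepoint`, `auc_delta`, `auc_delta_sd`,
#'   `n_replicates`), ordered by phage then timepoint.
#' @export
baseline_divergence <- function(spectra, baseline_timepoint = NULL,
                                grid = NULL) {
  need <- c("phage_id", "timepoint", "size_nm", "intensity")
  miss <- setdiff(need, names(spectra))
  if (length(miss) > 0) {
    abort(sprintf("`spectra` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!"replicate" %in% names(spectra)) spectra$replicate <- 1L
  if (is.null(baseline_timepoint)) {
    baseline_timepoint <- min(spectra$timepoint)
  }

  purrr::map_dfr(split(spectra, spectra$phage_id), function(ph) {
    base <- ph %>% filter(.data$timepoint == baseline_timepoint)
    if (nrow(base) == 0) {
      abort(sprintf("phage '%s' has no baseline at timepoint %s",
                    ph$phage_id[1L], format(baseline_timepoint)))
    }
    base_avg <- average_replicates(
      base %>% mutate(sample = as.character(.data$replicate)),
      label = "baseline", grid = grid
    )
    purrr::map_dfr(split(ph, ph$timepoint), function(tp) {
      reps <- tp %>% mutate(sample = as.character(.data$replicate))
      avg <- average_replicates(reps, label = "tp", grid = grid)
      rep_ids <- unique(reps$sample)
      rep_vals <- purrr::map_dbl(rep_ids, function(r) {
        as.numeric(auc_delta(reps %>% filter(.data$sample == r), base_avg,
                             grid = grid))
      })
      tibble(
        phage_id = ph$phage_id[1L],
        timepoint = tp$timepoint[1L],
        auc_delta = as.numeric(auc_delta(avg, base_avg, grid = grid)),
        auc_delta_sd = if (length(rep_vals) > 1) sd(rep_vals) else NA_real_,
        n_replicates = length(rep_ids)
      )
    })
  }) %>%
    arrange(.data$phage_id, .data$timepoint)
}
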
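#' Read DLS size-intensity spectra from CSV
#'
#' Parses Zetasizer-export-style tables into the package's tidy spectrum
#' format: one row per (sample, size bin), columns `sample`, `size_nm`,
#' `intensity`. Two dialects are supported:
#'
#' * `"wide"` — first column is the size bin (nm), every remaining column is
#'   one spectrum named by its header.
#' * `"long"` — columns `sample`, `size_nm`, `intensity` (other columns are
#'   ignored).
#'
#' Non-numeric header rows (e.g. a units row below the header) are skipped.
#' Imported spectra whose total intensity differs from 100 by more than 0.1%
#' are renormalized to area 100 with a warning; exact instrument exports are
#' left untouched.
#'
#' @param path Path to a UTF-8 CSV file. Sizes must be in nm, decimal point
#'   only.
#' @param dialect `"wide"` or `"long"`; `"auto"` (default) picks `"long"` when
#'   the header contains `sample`, `size_nm` and `intensity`.
#' @param renormalize Renormalize off-100 spectra (default TRUE, with a
#'   warning). Set FALSE to keep raw intensities.
#' @return A tibble with columns `sample` (character), `size_nm`, `intensity`,
#'   sizes strictly increasing within each sample.
#' @seealso [write_spectra_csv()] for the exact-round-trip writer,
#'   [spectra_summary()] for per-sample totals and normalization status.
#' @export
read_spectra_csv <- function(path, dialect = c("auto", "wide", "long"),
                             renormalize = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0 || ncol(raw) == 0) abort(sprintf("Empty file: %s", path))

  if (dialect == "auto") {
    dialect <- if (all(c("sample", "size_nm", "intensity") %in% names(raw))) {
      "long"
    } else {
      "wide"
    }
  }

  spectra <- if (dialect == "wide") parse_wide(raw) else parse_long(raw)
  validate_spectra(spectra)

  if (renormalize) {
    sums <- spectra %>%
      group_by(.data$sample) %>%
      summarise(total = sum(.data$intensity), .groups = "drop")
    off <- sums$sample[abs(sums$total - 100) > 0.1]
    if (length(off) > 0) {
      warn(sprintf(
        "Renormalizing %d spectra whose area differs from 100 by > 0.1%%: %s",
        length(off), paste(off, collapse = ", ")
      ))
      spectra <- spectra %>%
        group_by(.data$sample) %>%
        mutate(intensity = if (abs(sum(.data$intensity) - 100) > 0.1) {
          .data$intensity * 100 / sum(.data$intensity)
        } else {
          .data$intensity
        }) %>%
        ungroup()
    }
  }
  spectra
}

parse_wide <- function(raw) {
  size <- suppressWarnings(as.numeric(raw[[1L]]))
  keep <- !is.na(size) # drops units rows and other non-numeric headers
  if (!any(keep)) abort("No numeric size rows found in wide CSV.")
  size <- size[keep]
  if (any(diff(size) <= 0)) abort("Size column must be strictly increasing (nm).")
  samples <- names(raw)[-1L]
  if (length(samples) == 0) abort("Wide CSV has no spectrum columns.")
  purrr::map_dfr(samples, function(s) {
    vals <- suppressWarnings(as.numeric(raw[[s]][keep]))
    check_intensities(vals, which(keep), s)
    tibble(sample = s, size_nm = size, intensity = vals)
  })
}

parse_long <- function(raw) {
  need <- c("sample", "size_nm", "intensity")
  if (!all(need %in% names(raw))) {
    abort("Long CSV must have columns sample, size_nm, intensity.")
  }
  size <- suppressWarnings(as.numeric(raw$size_nm))
  keep <- !is.na(size)
  if (!any(keep)) abort("No numeric size rows found in long CSV.")
  out <- tibble(
    sample = as.character(raw$sample[keep]),
    size_nm = size[keep],
    intensity = suppressWarnings(as.numeric(raw$intensity[keep]))
  )
  check_intensities(out$intensity, which(keep), "long CSV")
  bad <- out %>%
    group_by(.data$sample) %>%
    summarise(ok = all(diff(.data$size_nm) > 0), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-increasing sizes in sample(s): %s",
                  paste(bad$sample, collapse = ", ")))
  }
  out
}

check_intensities <- function(vals, rows, label) {
  if (any(is.na(vals))) {
    abort(sprintf("Non-numeric intensity in %s at data row %d.",
                  label, rows[which(is.na(vals))[1L]]))
  }
  if (any(vals < 0)) {
    abort(sprintf("Negative intensity in %s at data row %d.",
                  label, rows[which(vals < 0)[1L]]))
  }
}

#' Write spectra to long-format CSV
#'
#' Values round-trip exactly through [read_spectra_csv()]: readr writes the
#' shortest decimal representation that reparses to the same double.
#'
#' @param spectra Spectra tibble (`sample`, `size_nm`, `intensity`, any extra
#'   columns are preserved).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  validate_spectra(spectra)
  readr::write_csv(spectra, path, progress = FALSE)
  invisible(path)
}

#' Per-sample totals and normalization status
#'
#' @param spectra Spectra tibble.
#' @param tol Absolute tolerance on the area-100 check (default 1e-3, the
#'   import-time convention).
#' @return Tibble with one row per sample: `sample`, `n_bins`, `total`
#'   (summed intensity), `normalized` (TRUE when `|total - 100| <= tol`).
#' @export
spectra_summary <- function(spectra, tol = 1e-3) {
  validate_spectra(spectra)
  spectra %>%
    group_by(.data$sample) %>%
    summarise(
      n_bins = dplyr::n(),
      total = sum(.data$intensity),
      .groups = "drop"
    ) %>%
    mutate(normalized = abs(.data$total - 100) <= tol)
}

# shared structural checks for the tidy spectrum format
validate_spectra <- function(spectra, arg = "spectra") {
  if (!is.data.frame(spectra)) abort(sprintf("`%s` must be a data frame.", arg))
  need <- c("sample", "size_nm", "intensity")
  miss <- setdiff(need, names(spectra))
  if (length(miss) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", arg,
                  paste(miss, collapse = ", ")))
  }
  if (nrow(spectra) == 0) abort(sprintf("`%s` has no rows.", arg))
  if (any(!is.finite(spectra$size_nm)) || any(spectra$size_nm <= 0)) {
    abort(sprintf("`%s`: sizes must be finite and positive (nm).", arg))
  }
  if (any(!is.finite(spectra$intensity))) {
    abort(sprintf("`%s`: intensities must be finite.", arg))
  }
  if (any(spectra$intensity < 0)) {
    abort(sprintf("`%s`: intensities must be non-negative.", arg))
  }
  invisible(spectra)
}

# extract the single sample in `spectra`, erroring otherwise
single_spectrum <- function(spectra, arg = "spectra") {
  validate_spectra(spectra, arg)
  ids <- unique(spectra$sample)
  if (length(ids) != 1) {
    abort(sprintf(
      "`%s` must contain exactly one sample (found %d: %s). Filter or average replicates first.",
      arg, length(ids), paste(head(ids, 5), collapse = ", ")
    ))
  }
  sp <- spectra[order(spectra$size_nm), , drop = FALSE]
  if (any(diff(sp$size_nm) <= 0)) {
    abort(sprintf("`%s`: duplicate size bins within a sample.", arg))
  }
  sp
}
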
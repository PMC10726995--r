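#' Canonical synthetic phage spectra
#'
#' Deterministic, noise-free spectra emulating well-characterized phage
#' preparations, for examples and end-to-end tests. These are synthetic
#' reconstructions from published summary features (peak positions and
#' qualitative composition), not instrument data; peak widths are
#' implementation constants (gsd 1.25 for virion-scale peaks, 2.0 for
#' aggregates), and baseline modes not reported for TIVP-H6 and OMKO1 are
#' package constants.
#'
#' Available fixtures:
#' * `LPS5_intact` — single virion peak at ~100 nm.
#' * `LPS5_sonicated` — virion peak lost; fragments at 90 nm plus dominant
#'   aggregates spanning ~500-8,000 nm.
#' * `TIVP_H6` — single virion peak (110 nm constant).
#' * `OMKO1` — single virion peak (160 nm constant).
#' * `T6_aged` — single peak at 200 nm.
#' * `T3_predicted_baseline` — predicted baseline: Gaussian (in log-size)
#'   centered at 60 nm.
#'
#' @param name Fixture name (see above).
#' @param grid [dls_grid()] to render on (default grid).
#' @return One-sample spectra tibble, area 100; calls are bit-reproducible.
#' @examples
#' intact <- phage_fixture("LPS5_intact")
#' damaged <- phage_fixture("LPS5_sonicated")
#' auc_delta(intact, damaged) # large divergence: the virion peak is lost
#' @export
phage_fixture <- function(name, grid = dls_grid()) {
  components <- switch(
    name,
    LPS5_intact = species_component(100, 1.25),
    LPS5_sonicated = bind_rows(
      species_component(90, 1.25, weight = 0.3),
      species_component(2000, 2.0, weight = 0.7)
    ),
    TIVP_H6 = species_component(110, 1.25),
    OMKO1 = species_component(160, 1.25),
    T6_aged = species_component(200, 1.25),
    T3_predicted_baseline = species_component(60, 1.25),
    abort(sprintf(
      "Unknown fixture '%s'. Available: LPS5_intact, LPS5_sonicated, TIVP_H6, OMKO1, T6_aged, T3_predicted_baseline",
      name
    ))
  )
  mixture_spectrum(components, grid, label = name)
}
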
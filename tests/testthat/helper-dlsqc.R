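# shared fixtures, built in code

# one-sample spectra tibble from raw intensities on a given grid
spec_tbl <- function(intensity, grid = dls_grid(10, 1000, length(intensity)),
                     label = "s") {
  tibble::tibble(sample = label, size_nm = grid$centers, intensity = intensity)
}

# random normalized spectrum on an n-bin grid (reproducible via caller's seed)
random_spectrum <- function(n_bins = 5, label = "s",
                            grid = dls_grid(10, 1000, n_bins)) {
  v <- stats::runif(n_bins)
  spec_tbl(v * 100 / sum(v), grid = grid, label = label)
}

# smooth lognormal test peak
peak_spectrum <- function(mode_nm = 100, gsd = 1.3, grid = dls_grid(),
                          label = "peak") {
  mixture_spectrum(species_component(mode_nm, gsd), grid, label = label)
}

default_noise_free_config <- function(seed = 1L) {
  decay_config(noise_sd_intensity = 0, noise_sd_titer = 0, seed = seed)
}
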
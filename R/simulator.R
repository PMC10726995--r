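#' Lognormal mixture components and spectra
#'
#' The simulator models a phage preparation as a mixture of particle species,
#' each a lognormal peak in hydrodynamic diameter (i.e. Gaussian in
#' log10-size, the shape intact virions present on a DLS export):
#' an intact-virion peak, a sub-virion fragment peak, and a broad aggregate
#' peak. [species_component()] describes one species; [mixture_spectrum()]
#' renders a weighted mixture onto a size grid as an area-100 spectrum.
#'
#' @param mode_nm Peak location (lognormal median), nm; must be positive.
#' @param gsd Geometric standard deviation (> 1); the Gaussian SD in
#'   log10-diameter is `log10(gsd)`.
#' @param weight Fraction of spectrum area carried by the species (0-1).
#' @return `species_component()`: a one-row tibble (`mode_nm`, `gsd`,
#'   `weight`).
#' @export
species_component <- function(mode_nm, gsd, weight = 1) {
  if (!is.finite(mode_nm) || mode_nm <= 0) abort("`mode_nm` must be > 0.")
  if (!is.finite(gsd) || gsd <= 1) abort("`gsd` must be > 1.")
  if (!is.finite(weight) || weight < 0 || weight > 1) {
    abort("`weight` must be in [0, 1].")
  }
  tibble(mode_nm = mode_nm, gsd = gsd, weight = weight)
}

#' @rdname species_component
#' @param components Tibble of components (rows from [species_component()]);
#'   weights must sum to 1 within 1e-9 and every mode must lie inside the
#'   grid span.
#' @param grid A [dls_grid()].
#' @param label Sample label for the rendered spectrum.
#' @return `mixture_spectrum()`: a one-sample spectra tibble, area 100.
#' @export
mixture_spectrum <- function(components, grid, label = "mixture") {
  if (!is.data.frame(components) ||
      !all(c("mode_nm", "gsd", "weight") %in% names(components))) {
    abort("`components` must have columns mode_nm, gsd, weight.")
  }
  if (abs(sum(components$weight) - 1) > 1e-9) {
    abort("component weights must sum to 1")
  }
  if (!is_dls_grid(grid)) abort("`grid` must be a dls_grid.")
  span <- range(grid$edges)
  if (any(components$mode_nm < span[1L] | components$mode_nm > span[2L])) {
    abort("component mode outside the grid span")
  }
  tibble(
    sample = label,
    size_nm = grid$centers,
    intensity = .mixture_vec(components, grid)
  )
}

# Each species' binned mass is normalized to area 100 before weighting, so a
# species carries exactly `weight` of the total area regardless of grid
# truncation, and mixtures are exactly linear in their weights.
.mixture_vec <- function(components, grid) {
  lc <- log10(grid$centers)
  w <- grid_log_widths(grid)
  out <- rep(0, length(lc))
  for (j in seq_len(nrow(components))) {
    mass <- dnorm(lc, mean = log10(components$mode_nm[j]),
                  sd = log10(components$gsd[j])) * w
    out <- out + components$weight[j] * .normalize_vec(mass)
  }
  out
}

#' Configuration for the phage-decay spectrum simulator
#'
#' Bundles the species mixture, the damage-to-titer coupling and the noise
#' model for [simulate_decay()]. The defaults encode a realistic decaying
#' phage preparation: an intact virion peak at 100 nm, fragments at 90 nm,
#' aggregates centered at 2,000 nm spanning the 500-8,000 nm band, 80% of
#' displaced mass going to aggregates, full damage costing 8 log10 PFU/mL,
#' ~5% multiplicative replicate jitter on intensities, and 0.3 log10
#' plaque-assay noise on titers.
#'
#' @param intact,fragment,aggregate [species_component()] rows describing the
#'   three species (their `weight` fields are ignored; weights come from the
#'   damage parameter).
#' @param a_frac Fraction of damaged mass that aggregates (vs fragments).
#' @param titer_slope Log10 titer loss at full damage (lambda = 1).
#' @param noise_sd_intensity SD of the per-bin multiplicative lognormal
#'   replicate jitter (on the log scale); 0 disables noise.
#' @param noise_sd_titer SD of the additive log10 titer noise.
#' @param seed Integer seed; all randomness in [simulate_decay()] derives
#'   from it.
#' @param grid [dls_grid()] on which spectra are rendered.
#' @return A `decay_config` list.
#' @export
decay_config <- function(intact = species_component(100, 1.25),
                         fragment = species_component(90, 1.25),
                         aggregate = species_component(2000, 2.0),
                         a_frac = 0.8,
                         titer_slope = 8,
                         noise_sd_intensity = 0.05,
                         noise_sd_titer = 0.3,
                         seed = 1L,
                         grid = dls_grid()) {
  if (!is.finite(a_frac) || a_frac < 0 || a_frac > 1) {
    abort("`a_frac` must be in [0, 1].")
  }
  if (noise_sd_intensity < 0 || noise_sd_titer < 0) {
    abort("noise parameters must be >= 0")
  }
  if (!is.finite(titer_slope)) abort("`titer_slope` must be finite.")
  structure(
    list(intact = intact, fragment = fragment, aggregate = aggregate,
         a_frac = a_frac, titer_slope = titer_slope,
         noise_sd_intensity = noise_sd_intensity,
         noise_sd_titer = noise_sd_titer,
         seed = as.integer(seed), grid = grid),
    class = "decay_config"
  )
}

#' Simulate DLS spectra and titers of decaying phage preparations
#'
#' Each simulated sample carries a latent damage fraction lambda in \[0, 1\].
#' Its spectrum is the mixture with weights `intact = 1 - lambda`,
#' `aggregate = lambda * a_frac`, `fragment = lambda * (1 - a_frac)` — linear
#' in lambda, so with zero noise both AUC-delta against baseline and the true
#' titer loss (`titer_slope * lambda`) are exactly proportional to lambda and
#' to each other. Replicates receive multiplicative lognormal intensity
#' jitter and are renormalized; titers receive additive Gaussian log10 noise.
#' A zero-damage baseline sample is always included, and each damaged
#' sample's AUC-delta against the averaged baseline replicates is returned
#' ready for [fit_linear()] / [fit_logistic()].
#'
#' All randomness derives from `config$seed`: identical configs give
#' bit-identical output.
#'
#' @param config A [decay_config()].
#' @param n_samples Number of damaged samples (>= 1).
#' @param n_replicates Replicate spectra per sample (>= 1; DLS convention
#'   is 3).
#' @param damage Optional vector of damage fractions (length `n_samples`,
#'   each in \[0, 1\]); drawn uniformly when NULL.
#' @return A `dls_sim` list: `spectra` (tibble `sample`, `replicate`,
#'   `size_nm`, `intensity`), `samples` (tibble `sample`, `damage`,
#'   `auc_delta`, `titer_loss_log10`, `censored`), plus the `config` and
#'   `grid` used.
#' @export
simulate_decay <- function(config, n_samples, n_replicates = 3,
                           damage = NULL) {
  if (!inherits(config, "decay_config")) {
    abort("`config` must come from decay_config().")
  }
  if (n_samples < 1) abort("`n_samples` must be >= 1.")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  set.seed(config$seed)

  if (is.null(damage)) {
    damage <- runif(n_samples)
  } else {
    if (length(damage) != n_samples) {
      abort("`damage` must have length `n_samples`.")
    }
    if (any(!is.finite(damage)) || any(damage < 0) || any(damage > 1)) {
      abort("`damage` values must lie in [0, 1].")
    }
  }

  grid <- config$grid
  nb <- grid$n_bins
  ids <- c("baseline", sprintf("s%03d", seq_len(n_samples)))
  lambdas <- c(0, damage)

  clean <- vapply(lambdas, function(l) {
    comps <- decay_mixture(config, l)
    .mixture_vec(comps, grid)
  }, numeric(nb))

  # replicate spectra as a bins x (sample, replicate) matrix; jitter drawn
  # column-major so draws match a per-replicate loop
  n_ids <- length(ids)
  rep_mat <- clean[, rep(seq_len(n_ids), each = n_replicates), drop = FALSE]
  if (config$noise_sd_intensity > 0) {
    jit <- matrix(exp(rnorm(nb * n_ids * n_replicates, 0,
                            config$noise_sd_intensity)), nrow = nb)
    rep_mat <- rep_mat * jit
    rep_mat <- sweep(rep_mat, 2, colSums(rep_mat), "/") * 100
  }
  spectra <- tibble(
    sample = rep(ids, each = n_replicates * nb),
    replicate = rep(rep(seq_len(n_replicates), each = nb), times = n_ids),
    size_nm = rep(grid$centers, times = n_ids * n_replicates),
    intensity = as.vector(rep_mat)
  )
  avg <- vapply(seq_along(ids), function(i) {
    cols <- ((i - 1) * n_replicates + 1):(i * n_replicates)
    .normalize_vec(rowMeans(rep_mat[, cols, drop = FALSE]))
  }, numeric(nb))

  auc <- vapply(seq_along(ids), function(i) {
    .auc_delta_vec(avg[, i], avg[, 1L])
  }, numeric(1))

  loss <- config$titer_slope * lambdas
  if (config$noise_sd_titer > 0) {
    loss <- loss + rnorm(length(loss), 0, config$noise_sd_titer)
  }
  loss[1L] <- 0 # baseline defines zero loss

  samples <- tibble(
    sample = ids, damage = lambdas, auc_delta = auc,
    titer_loss_log10 = loss, censored = FALSE
  )
  structure(list(spectra = spectra, samples = samples, config = config,
                 grid = grid),
            class = "dls_sim")
}

# mixture weights as a function of the damage fraction
decay_mixture <- function(config, lambda) {
  bind_rows(
    config$intact %>% mutate(weight = 1 - lambda),
    config$fragment %>% mutate(weight = lambda * (1 - config$a_frac)),
    config$aggregate %>% mutate(weight = lambda * config$a_frac)
  ) %>% filter(.data$weight > 0)
}

#' @export
print.dls_sim <- function(x, ...) {
  cat(sprintf(
    "<dls_sim> %d samples (+ baseline) x %d replicates on %d bins; titer slope %g, seed %d\n",
    nrow(x$samples) - 1L,
    sum(x$spectra$sample == "baseline") / x$grid$n_bins,
    x$grid$n_bins, x$config$titer_slope, x$config$seed
  ))
  invisible(x)
}

#' Paired observations from a simulation
#'
#' Extracts the (AUC-delta, titer loss) pairs of the damaged samples, the
#' input shape expected by [fit_linear()], [fit_logistic()] and
#' [threshold_sweep()].
#'
#' @param sim A `dls_sim` from [simulate_decay()].
#' @param phage_id Label recorded in the `phage_id` column.
#' @return Pairs tibble (`phage_id`, `sample`, `auc_delta`,
#'   `titer_loss_log10`, `censored`), baseline excluded.
#' @export
sim_pairs <- function(sim, phage_id = "simulated") {
  if (!inherits(sim, "dls_sim")) abort("`sim` must come from simulate_decay().")
  sim$samples %>%
    filter(.data$sample != "baseline") %>%
    mutate(phage_id = phage_id) %>%
    select(all_of(c("phage_id", "sample", "auc_delta", "titer_loss_log10",
                    "censored")))
}
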
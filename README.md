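# dlsqc — quality control of phage preparations from DLS spectra

Therapeutic bacteriophage preparations decay: virions fragment into
non-infectious debris or aggregate into large, sterically inhibited clusters,
and either way the preparation loses lytic titer. Both endpoints reshape the
particle size distribution that a benchtop dynamic light scattering (DLS)
instrument reports in minutes, whereas the plaque assay that measures titer
takes a day. `dlsqc` is for phage biologists, therapy labs and QC engineers
who want to exploit that gap: it quantifies spectral change, calibrates it
against measured titer loss, and predicts the bioactivity loss of new samples
from their spectra alone.

## The statistic and the models

Every DLS size-intensity spectrum is normalized to total area 100 over
log-spaced diameter bins. The divergence between two spectra *a*, *b* on a
common grid is

> AUCΔ(a, b) = Σᵢ |aᵢ − bᵢ|  ∈ [0, 200]

— 0 for identical spectra, 200 for disjoint ones (each spectrum has area
100, so at most 200 units of non-overlap). On top of AUCΔ the package fits:

* a **linear calibration** of titer loss (log10 PFU/mL) on AUCΔ — OLS with
  the two-tailed Pearson test, regression prediction intervals for new
  samples, extrapolation flags, and a Wald–Wolfowitz runs test for departure
  from linearity (exact for n ≤ 30);
* **threshold logistic classifiers** P(loss > L | AUCΔ) for
  L ∈ {0.5, …, 3} log10 — odds change per AUCΔ unit (100·(e^β₁ − 1)) with
  Wald 95% CI, Tjur pseudo-R², and ROC-AUC via the Mann–Whitney rank
  statistic, with explicit complete-separation detection;
* a **decay simulator** — three-species lognormal mixtures (intact virions,
  fragments, aggregates) driven by a latent damage fraction coupled linearly
  to titer loss — that makes the whole pipeline testable end to end without
  instrument data.

## Worked example

```r
library(dlsqc)

# simulate a decaying preparation: 30 samples, 3 DLS replicates each
sim   <- simulate_decay(decay_config(seed = 42), n_samples = 30)
pairs <- sim_pairs(sim)   # (AUC-delta, titer loss) per sample

fit <- fit_linear(pairs)
fit
#> Linear DLS calibration: titer_loss_log10 ~ auc_delta
#>   slope     0.0483082 log10 PFU/mL per AUC-delta unit
#>   intercept 0.0803497 log10 PFU/mL
#>   r = 0.9913, r^2 = 0.9826, two-tailed Pearson p = 3.47e-26, n = 30
#>   residual SD 0.3062 (df = 28), AUC-delta range [13.1, 159]

predict_titer_loss(fit, c(40, 120))
#> # A tibble: 2 × 6
#>   auc_delta predicted_loss_log10 lower upper level extrapolated
#>       <dbl>                <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1        40                 2.01  1.36  2.67  0.95 FALSE
#> 2       120                 5.88  5.24  6.52  0.95 FALSE
```

A sample with AUCΔ = 120 against its baseline is predicted to have lost
5.9 log10 PFU/mL (95% prediction interval 5.2–6.5) — a preparation that
should not be released. The runs test on this fit
(`runs_test_linearity(fit)`) gives p = 1 (16 runs in 30 residuals): no
evidence of departure from linearity. The same pairs support a classifier
(here at n = 100 samples for stable maximum likelihood):

```r
pairs100 <- sim_pairs(simulate_decay(decay_config(seed = 42), n_samples = 100))
fit_logistic(pairs100, threshold_log10 = 3)
#> Logistic DLS classifier: P(titer loss > 3 log10) ~ auc_delta
#>   odds change per AUC-delta unit: +43.71% (95% CI 3.62% to 99.33%), Wald p = 0.0298
#>   Tjur R^2 = 0.928, ROC-AUC = 0.998, n = 100 (64 positive)
```

Each extra AUCΔ unit multiplies the odds of a >3-log loss by ~1.44. Synthetic
canonical spectra are built in: an intact preparation versus a sonicated one
(virion peak lost to fragments and 500–8,000 nm aggregates) diverges by

```r
auc_delta(phage_fixture("LPS5_intact"), phage_fixture("LPS5_sonicated"))
#> AUC-delta(LPS5_intact, LPS5_sonicated) = 140  [0 = identical, 200 = disjoint]
```

All results have `tidy()`/`glance()` methods and `autoplot()` figures
(calibration scatter with prediction band; ROC curves); `plot_spectra()`
overlays spectra on a log-diameter axis. A command-line workflow
(`compare` / `train` / `predict` / `simulate`) lives at
`system.file("cli", "dlsqc.R", package = "dlsqc")` and reads/writes plain
CSV, JSON models, and YAML simulator configs.

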
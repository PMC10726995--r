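---
title: "DLS-based quality control of phage preparations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DLS-based quality control of phage preparations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlsqc)
```

## The problem

Therapeutic bacteriophage preparations lose lytic activity in storage and in
response to environmental stress. Two physical endpoints dominate that decay:
virions fragment into sub-virion debris, or they aggregate into large,
sterically inhibited clusters (hundreds of nm to several µm). Both endpoints
change the particle size distribution of the preparation, and both can be seen
on a benchtop dynamic light scattering (DLS) instrument long before a plaque
assay result is available. `dlsqc` turns that observation into a quantitative
quality-control workflow: summarize the change in a DLS spectrum with a single
divergence statistic, calibrate that statistic against measured titer loss
(log10 PFU/mL), and use the calibration to predict the bioactivity loss of new
samples from their spectra alone.

## The divergence statistic

A DLS size-intensity spectrum is a histogram of relative scattered-light
intensity over log-spaced hydrodynamic-diameter bins, normalized here so that
the bin values sum to 100. For two spectra $a$ and $b$ on a common grid the
package computes

$$\mathrm{AUC\Delta}(a, b) \;=\; \sum_i \lvert a_i - b_i \rvert ,$$

the L1 distance between the two histograms. Because each spectrum carries
area 100, the statistic lives on $[0, 200]$: 0 for identical spectra, 200
when the supports are disjoint. It is symmetric and satisfies the triangle
inequality, so it behaves like a metric on normalized spectra; the tests
exercise all three properties against brute-force oracles.

Two numerical conventions matter:

* **Common gridding.** Bin-wise differences are only defined on a shared
  binning. When two spectra arrive on different grids, both are resampled
  onto a 70-bin geometric grid spanning the union of their supports.
  Intensities are treated as densities per unit $\log_{10}$(diameter) during
  interpolation, which makes resampling exact for spectra that are piecewise
  linear in log-size and conserves total area to $10^{-6}$ for any
  overlapping target grid. Values interpolated outside a spectrum's support
  are zero: the instrument reported no mass there. For smooth spectra the
  statistic is stable under grid refinement (70 vs 280 bins differ by under
  2%).
* **Replicates are averaged first.** DLS measurements come in replicates
  (typically $n = 3$). The package normalizes each replicate, averages them
  bin-wise, renormalizes, and computes one AUCΔ per sample against the
  averaged baseline. The SD of replicate-vs-averaged-baseline values is
  reported as spread alongside the point value.

Floating-point excursions above 200 (possible at the $10^{-13}$ level after
resampling) are clamped.

## Calibration models

**Linear.** `fit_linear()` regresses titer loss (log10 PFU/mL, positive =
loss) on AUCΔ by ordinary least squares and reports the two-tailed Pearson
correlation test. Predictions for new samples come with the standard
regression prediction interval
$\hat y \pm t_{1-\alpha/2,\,n-2}\, s \sqrt{1 + 1/n + (x - \bar x)^2 / S_{xx}}$
at a default 95% level, and any AUCΔ outside the training range is flagged:
the standard curve is least trustworthy where it was not sampled. Departure
from linearity is assessed with a Wald–Wolfowitz runs test on the signs of
residuals ordered by AUCΔ — exact enumeration of the runs distribution for up
to 30 non-zero residuals, continuity-corrected normal approximation above;
exactly-zero residuals are dropped, and an all-zero residual vector (a
perfect fit) yields a vacuous $p = 1$ with a note.

**Threshold logistic.** Because linear associations can be driven by data
clustered at the extremes, the same pairs can be modeled as classifiers:
$y = 1$ when the loss strictly exceeds a threshold $L \in
\{0.5, 1, 1.5, 2, 2.5, 3\}$ log10. `fit_logistic()` fits
$\mathrm{logit}\, P(y=1) = \beta_0 + \beta_1 \cdot \mathrm{AUC\Delta}$ by
IRLS (deviance tolerance $10^{-10}$, 100 iterations max) and reports the
effect as the percent change in odds per AUCΔ unit,
$100(e^{\beta_1} - 1)$, with a Wald 95% CI on the same scale — Wald rather
than profile likelihood, matching how such odds-ratio percentages are
conventionally reported. Model quality is summarized by Tjur's
$R^2$ (mean fitted probability among positives minus negatives) and by the
ROC-AUC computed from the Mann–Whitney rank statistic with midrank tie
handling; `roc_curve()` reproduces the same area by trapezoidal integration
to $10^{-9}$. Complete separation is detected (fitted probabilities
reproducing the labels to $10^{-6}$, or $|\beta_1| > 50$) and flagged with a
warning rather than allowed to diverge silently; Wald statistics are
meaningless in that regime.

**Censored observations.** Samples that lost all measurable activity carry a
detection-limit bound rather than a titer. Their binary outcome is
unambiguous, so they are always included in logistic fits; linear fits
include them by default (loss set to the baseline-minus-detection-limit
bound) with `include_censored = FALSE` to exclude.

## The decay simulator

`simulate_decay()` exists so every downstream stage can be validated without
instrument data. It models a preparation as a three-species lognormal mixture
in diameter — Gaussian peaks in $\log_{10}$-size, the shape a clean virion
population presents on a DLS export:

| parameter | default | rationale |
|---|---|---|
| intact mode | 100 nm | virion-scale hydrodynamic diameter of clinical-trial phages |
| fragment mode | 90 nm | sub-virion debris sits just below the virion peak |
| aggregate mode / gsd | 2,000 nm / 2.0 | broad cluster band spanning ~500–8,000 nm |
| virion gsd | 1.25 | narrow monodisperse peak |
| `a_frac` | 0.8 | aggregates dominate the displaced intensity |
| `titer_slope` | 8 log10 | full damage ≈ complete loss from a $10^{10}$ PFU/mL stock |
| `noise_sd_intensity` | 0.05 | ~5% replicate CV, typical of benchtop DLS |
| `noise_sd_titer` | 0.3 log10 | plaque-assay replicate spread |

A latent damage fraction $\lambda \in [0,1]$ sets the mixture weights
(intact $1-\lambda$, aggregate $\lambda \cdot a_\mathrm{frac}$, fragment the
remainder) and the mean titer loss ($\mathrm{slope} \cdot \lambda$). Each
species' binned mass is normalized before weighting, so the rendered spectrum
is *exactly* linear in $\lambda$; with noise off, AUCΔ against baseline is
exactly proportional to $\lambda$ and the linear calibration recovers
$r^2 = 1$ to machine precision — a sharp end-to-end invariant the tests
assert. Replicate noise is multiplicative lognormal per bin followed by
renormalization; titer noise is additive Gaussian in log10. All randomness
derives from the config seed, and identical configs produce bit-identical
output.

What the simulator deliberately does **not** emulate: aggregation kinetics,
scattering-intensity (Mie) weighting of large particles, instrument
polydispersity smoothing, correlated (non-independent) bin noise, and
baseline drift. Passing tests therefore demonstrate that the statistical
machinery is correct under the structural assumptions the calibration makes
(monotone spectral divergence coupled linearly to loss), not that any
particular instrument or phage obeys those assumptions.

## Validation choices and problem sizes

The package validates itself at sizes chosen to make Monte-Carlo error small
relative to the tolerances asserted: 1,000 random spectrum pairs for the
metric properties; a 10,000-shuffle permutation test against the Pearson
p-value at $n = 20$; slope recovery and CI coverage over 200 simulation seeds
at $n = 100$ samples × 3 replicates (observed bias well under the 5% bound,
coverage inside 90–99%); and classifier sweeps over 100 seeds, where the mean
ROC-AUC increases with the loss threshold — higher losses are easier to
classify, matching the qualitative behavior expected of the method.

Synthetic canonical fixtures (`phage_fixture()`) reconstruct well-known
spectra — an intact 100 nm virion peak, a sonicated preparation with 90 nm
fragments plus a 500–8,000 nm aggregate band, an aged stock peaking at
200 nm, a predicted 60 nm baseline — from published summary features. Peak
widths are implementation constants (the published spectra are shown but not
parameterized), as are the 110/160 nm baseline modes of the two fixtures
whose diameters are not printed anywhere.

## Known limitations

* AUCΔ is a global L1 divergence: it cannot distinguish fragmentation from
  aggregation by itself (use `peak_summary()` for that), and it saturates at
  200 once supports are disjoint, so calibrations flatten for catastrophic
  damage.
* Calibrations are phage- and perturbation-specific; the package makes no
  attempt to transfer a standard curve across phages.
* The linear model treats AUCΔ as error-free; replicate jitter in the
  predictor attenuates the slope slightly (well under the tested 5% at
  default noise).
* DLS intensity weighting over-represents large particles; the statistic
  inherits that sensitivity, which is precisely why it detects aggregation
  early but also why volume- or number-weighted conclusions are out of
  scope.
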
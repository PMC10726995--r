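#' Threshold logistic classifier of titer loss from AUC-delta
#'
#' Treats titer loss as a binary outcome — 1 when the loss strictly exceeds
#' `threshold_log10` — and fits a single-predictor logistic regression on
#' AUC-delta by maximum likelihood (IRLS, deviance tolerance 1e-10, up to 100
#' iterations). Reported alongside the coefficients:
#'
#' * the percent change in the odds of exceeding the threshold per unit
#'   AUC-delta, `100 * (exp(beta1) - 1)`, with its Wald 95% CI on the same
#'   scale and the Wald p-value;
#' * Tjur's pseudo R-squared, the mean fitted probability among positives
#'   minus the mean among negatives;
#' * ROC-AUC computed from the Mann-Whitney rank statistic on the fitted
#'   probabilities (ties get rank 1/2).
#'
#' Complete separation does not diverge silently: when the fit reproduces the
#' labels (or |beta1| > 50) the result carries `separation = TRUE` and a
#' warning; Wald statistics are then unreliable.
#'
#' @param pairs Paired observations as in [fit_linear()]. Censored
#'   (complete-loss) observations are always included: their binary outcome
#'   is unambiguous.
#' @param threshold_log10 Loss threshold in log10 PFU/mL; the study's
#'   conventional grid is 0.5, 1, 1.5, 2, 2.5, 3.
#' @return A `dls_logistic` object: list with `threshold_log10`, `beta0`,
#'   `beta1`, `se_beta1`, `or_pct_per_unit`, `or_ci95`, `p_value`, `tjur_r2`,
#'   `roc_auc`, `n`, `n_pos`, `separation`, fitted probabilities, outcomes,
#'   training `pairs`, and the underlying `stats::glm` fit.
#' @export
fit_logistic <- function(pairs, threshold_log10) {
  pairs <- validate_pairs(pairs)
  if (length(threshold_log10) != 1 || !is.finite(threshold_log10) ||
      threshold_log10 <= 0) {
    abort("`threshold_log10` must be a single positive number.")
  }
  y <- as.integer(pairs$titer_loss_log10 > threshold_log10)
  if (length(unique(y)) < 2) {
    abort(sprintf(
      "degenerate outcome: all observations on one side of the %g-log threshold",
      threshold_log10
    ))
  }
  dat <- tibble(y = y, auc_delta = pairs$auc_delta)
  fit <- suppressWarnings(glm(
    y ~ auc_delta, family = stats::binomial(), data = dat,
    control = glm.control(epsilon = 1e-10, maxit = 100)
  ))
  b <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  p_hat <- fitted(fit)
  separation <- all(abs(y - p_hat) < 1e-6) || abs(b[2L]) > 50 || !fit$converged
  if (separation) {
    warn("Perfect separation detected: logistic slope is unbounded and Wald statistics are unreliable.")
  }
  z <- qnorm(0.975)
  structure(
    list(
      threshold_log10 = threshold_log10,
      beta0 = unname(b[1L]),
      beta1 = unname(b[2L]),
      se_beta1 = unname(se[2L]),
      or_pct_per_unit = 100 * (exp(unname(b[2L])) - 1),
      or_ci95 = 100 * (exp(unname(b[2L]) + c(-1, 1) * z * unname(se[2L])) - 1),
      p_value = 2 * pnorm(-abs(unname(b[2L]) / unname(se[2L]))),
      tjur_r2 = tjur_r2(y, p_hat),
      roc_auc = rank_roc_auc(y, p_hat),
      n = length(y),
      n_pos = sum(y),
      x_range = range(pairs$auc_delta),
      separation = separation,
      fitted_prob = as.numeric(p_hat),
      outcome = y,
      pairs = pairs,
      glm = fit
    ),
    class = "dls_logistic"
  )
}

# Tjur's coefficient of discrimination
tjur_r2 <- function(y, p_hat) {
  mean(p_hat[y == 1]) - mean(p_hat[y == 0])
}

# ROC-AUC as the Mann-Whitney rank statistic: P(score_pos > score_neg) with
# ties counted 1/2, computed from midranks
rank_roc_auc <- function(y, score) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.dls_logistic <- function(x, ...) {
  cat(sprintf("Logistic DLS classifier: P(titer loss > %g log10) ~ auc_delta\n",
              x$threshold_log10))
  cat(sprintf(
    "  odds change per AUC-delta unit: %+.2f%% (95%% CI %.2f%% to %.2f%%), Wald p = %.3g\n",
    x$or_pct_per_unit, x$or_ci95[1L], x$or_ci95[2L], x$p_value
  ))
  cat(sprintf("  Tjur R^2 = %.3f, ROC-AUC = %.3f, n = %d (%d positive)\n",
              x$tjur_r2, x$roc_auc, x$n, x$n_pos))
  if (x$separation) cat("  WARNING: perfect separation; slope unbounded\n")
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `dls_logistic` object.
#' @param ... Unused.
#' @export
tidy.dls_logistic <- function(x, ...) {
  sm <- summary(x$glm)$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1L]),
    std.error = unname(sm[, 2L]),
    statistic = unname(sm[, 3L]),
    p.value = unname(sm[, 4L])
  )
}

#' @rdname fit_logistic
#' @export
glance.dls_logistic <- function(x, ...) {
  tibble(
    threshold_log10 = x$threshold_log10,
    or_pct_per_unit = x$or_pct_per_unit,
    or_ci_low = x$or_ci95[1L], or_ci_high = x$or_ci95[2L],
    p.value = x$p_value, tjur_r2 = x$tjur_r2, roc_auc = x$roc_auc,
    separation = x$separation, nobs = x$n, n_pos = x$n_pos
  )
}

#' Fit logistic classifiers across a grid of loss thresholds
#'
#' Sweeps [fit_logistic()] over titer-loss thresholds. Thresholds for which
#' one outcome class is empty are reported as skipped rows, not errors, so a
#' whole panel can be summarized in one call.
#'
#' @inheritParams fit_logistic
#' @param thresholds Thresholds in log10 PFU/mL (default
#'   `c(0.5, 1, 1.5, 2, 2.5, 3)`).
#' @return Tibble with one row per threshold: the [glance.dls_logistic()]
#'   columns plus `skipped`, and a `model` list-column holding each fitted
#'   `dls_logistic` (NULL when skipped).
#' @export
threshold_sweep <- function(pairs, thresholds = c(0.5, 1, 1.5, 2, 2.5, 3)) {
  if (length(thresholds) == 0) abort("`thresholds` must be non-empty.")
  pairs <- validate_pairs(pairs)
  purrr::map_dfr(thresholds, function(th) {
    fit <- tryCatch(fit_logistic(pairs, th), error = function(e) NULL)
    if (is.null(fit)) {
      tibble(
        threshold_log10 = th, or_pct_per_unit = NA_real_,
        or_ci_low = NA_real_, or_ci_high = NA_real_, p.value = NA_real_,
        tjur_r2 = NA_real_, roc_auc = NA_real_, separation = NA,
        nobs = nrow(pairs),
        n_pos = sum(pairs$titer_loss_log10 > th),
        skipped = TRUE, model = list(NULL)
      )
    } else {
      glance(fit) %>% mutate(skipped = FALSE, model = list(fit))
    }
  })
}

#' ROC curve of a fitted threshold classifier
#'
#' Sweeps the probability cutoff over the classifier's fitted probabilities
#' (equal scores grouped, cutoffs in decreasing order) and reports the false
#' and true positive rates. The trapezoidal area under the returned curve
#' equals the classifier's Mann-Whitney `roc_auc` to within 1e-9.
#'
#' @param classifier A fitted `dls_logistic`.
#' @return Tibble (`cutoff`, `fpr`, `tpr`) starting at (Inf, 0, 0) and ending
#'   at (min score, 1, 1).
#' @export
roc_curve <- function(classifier) {
  if (!inherits(classifier, "dls_logistic")) {
    abort("`classifier` must be a fitted dls_logistic.")
  }
  y <- classifier$outcome
  score <- classifier$fitted_prob
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  cuts <- sort(unique(score), decreasing = TRUE)
  tp <- cumsum(vapply(cuts, function(c) sum(y == 1 & score == c), numeric(1)))
  fp <- cumsum(vapply(cuts, function(c) sum(y == 0 & score == c), numeric(1)))
  tibble(
    cutoff = c(Inf, cuts),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
}

#' Probability of exceeding the loss threshold for new AUC-delta values
#'
#' Applies a fitted threshold classifier to new divergences:
#' `P(loss > threshold) = plogis(beta0 + beta1 * auc_delta)`. Values outside
#' the AUC-delta range seen in training are flagged as extrapolated with a
#' warning.
#'
#' @param classifier A `dls_logistic` (fitted or restored from JSON).
#' @param new_auc_delta Numeric vector in \[0, 200\].
#' @return Tibble (`auc_delta`, `prob_exceed`, `threshold_log10`,
#'   `extrapolated`).
#' @export
predict_exceed_prob <- function(classifier, new_auc_delta) {
  if (!inherits(classifier, "dls_logistic")) {
    abort("`classifier` must be a dls_logistic.")
  }
  if (any(!is.finite(new_auc_delta)) || any(new_auc_delta < 0) ||
      any(new_auc_delta > 200)) {
    abort("`new_auc_delta` must be finite and within [0, 200].")
  }
  x <- as.numeric(new_auc_delta)
  extrap <- x < classifier$x_range[1L] | x > classifier$x_range[2L]
  if (any(extrap)) {
    warn(sprintf(
      "%d prediction(s) outside the fitted AUC-delta range [%.3g, %.3g].",
      sum(extrap), classifier$x_range[1L], classifier$x_range[2L]
    ))
  }
  tibble(
    auc_delta = x,
    prob_exceed = plogis(classifier$beta0 + classifier$beta1 * x),
    threshold_log10 = classifier$threshold_log10,
    extrapolated = extrap
  )
}

# trapezoidal area under an ROC tibble
roc_trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}
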
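#' Linear calibration of titer loss on AUC-delta
#'
#' Fits the standard curve at the heart of the DLS-based quality-control
#' workflow: ordinary least squares of log10 titer loss on AUC-delta, with the
#' two-tailed Pearson correlation test for the significance of the linear
#' association. Titer loss is signed so that positive values are losses
#' (log10 decrease from baseline).
#'
#' @param pairs Tibble of paired observations with columns `auc_delta`
#'   (in \[0, 200\]) and `titer_loss_log10`; optional `phage_id`, `condition`
#'   and `censored` (TRUE when the loss is a detection-limit bound, i.e.
#'   complete titer loss). Needs n >= 3 and at least two distinct AUC-delta
#'   values.
#' @param include_censored Keep censored (complete-loss) observations in the
#'   fit (default TRUE; their loss is the baseline-minus-detection-limit
#'   bound).
#' @return A `dls_linear` object: list with `slope`, `intercept`, `r`,
#'   `r_squared`, `p_value` (two-tailed Pearson), `n`, `residual_sd`
#'   (n - 2 df), `df`, the design summaries used for prediction intervals
#'   (`x_mean`, `x_ssx`, `x_range`), the coefficient table, the training
#'   `pairs`, and the underlying `stats::lm` fit. Supports
#'   [generics::tidy()], [generics::glance()], [predict_titer_loss()],
#'   [runs_test_linearity()] and [ggplot2::autoplot()].
#' @examples
#' pairs <- tibble::tibble(auc_delta = c(0, 10, 20), titer_loss_log10 = c(0, 1, 2))
#' fit <- fit_linear(pairs)
#' fit$slope     # 0.1
#' fit$r_squared # 1
#' @export
fit_linear <- function(pairs, include_censored = TRUE) {
  pairs <- validate_pairs(pairs)
  if (!include_censored) pairs <- pairs %>% filter(!.data$censored)
  n <- nrow(pairs)
  if (n < 3) abort("Linear calibration needs at least 3 paired observations.")
  if (length(unique(pairs$auc_delta)) < 2) {
    abort("no variation in predictor: all auc_delta values identical")
  }

  fit <- lm(titer_loss_log10 ~ auc_delta, data = pairs)
  ct <- suppressWarnings(
    cor.test(pairs$auc_delta, pairs$titer_loss_log10, method = "pearson")
  )
  smry <- summary(fit)
  x <- pairs$auc_delta
  structure(
    list(
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r = unname(ct$estimate),
      r_squared = unname(ct$estimate)^2,
      p_value = ct$p.value,
      n = n,
      residual_sd = smry$sigma,
      df = n - 2L,
      x_mean = mean(x),
      x_ssx = sum((x - mean(x))^2),
      x_range = range(x),
      coef_table = smry$coefficients,
      pairs = pairs,
      lm = fit
    ),
    class = "dls_linear"
  )
}

validate_pairs <- function(pairs) {
  if (!is.data.frame(pairs)) abort("`pairs` must be a data frame.")
  need <- c("auc_delta", "titer_loss_log10")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0) {
    abort(sprintf("`pairs` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(pairs$auc_delta)) ||
      any(pairs$auc_delta < 0) || any(pairs$auc_delta > 200)) {
    abort("`auc_delta` must be finite and within [0, 200].")
  }
  if (any(!is.finite(pairs$titer_loss_log10))) {
    abort("`titer_loss_log10` must be finite.")
  }
  pairs <- as_tibble(pairs)
  if (!"censored" %in% names(pairs)) pairs$censored <- FALSE
  pairs
}

#' @export
print.dls_linear <- function(x, ...) {
  cat("Linear DLS calibration: titer_loss_log10 ~ auc_delta\n")
  cat(sprintf("  slope     %.6g log10 PFU/mL per AUC-delta unit\n", x$slope))
  cat(sprintf("  intercept %.6g log10 PFU/mL\n", x$intercept))
  cat(sprintf("  r = %.4f, r^2 = %.4f, two-tailed Pearson p = %.3g, n = %d\n",
              x$r, x$r_squared, x$p_value, x$n))
  cat(sprintf("  residual SD %.4g (df = %d), AUC-delta range [%.3g, %.3g]\n",
              x$residual_sd, x$df, x$x_range[1L], x$x_range[2L]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_linear
#' @param x A `dls_linear` object.
#' @param ... Unused.
#' @export
tidy.dls_linear <- function(x, ...) {
  ct <- x$coef_table
  tibble(
    term = c("(Intercept)", "auc_delta"),
    estimate = unname(ct[, 1L]),
    std.error = unname(ct[, 2L]),
    statistic = unname(ct[, 3L]),
    p.value = unname(ct[, 4L])
  )
}

#' @rdname fit_linear
#' @export
glance.dls_linear <- function(x, ...) {
  tibble(
    r = x$r, r.squared = x$r_squared, p.value = x$p_value,
    sigma = x$residual_sd, df.residual = x$df, nobs = x$n
  )
}

#' Predict titer loss from new AUC-delta values
#'
#' Applies a fitted linear calibration to new spectra divergences, returning
#' the point prediction and the regression prediction interval for a single
#' new observation. Predictions outside the AUC-delta range seen in training
#' are flagged (and warned about): calibrations are least reliable where the
#' standard curve was not sampled.
#'
#' @param model A `dls_linear` from [fit_linear()] (or loaded via
#'   [read_model_json()]).
#' @param new_auc_delta Numeric vector of AUC-delta values in \[0, 200\].
#' @param level Prediction-interval coverage (default 0.95).
#' @return Tibble (`auc_delta`, `predicted_loss_log10`, `lower`, `upper`,
#'   `level`, `extrapolated`).
#' @export
predict_titer_loss <- function(model, new_auc_delta, level = 0.95) {
  if (!inherits(model, "dls_linear")) {
    abort("`model` must be a fitted dls_linear calibration.")
  }
  if (any(!is.finite(new_auc_delta)) || any(new_auc_delta < 0) ||
      any(new_auc_delta > 200)) {
    abort("`new_auc_delta` must be finite and within [0, 200].")
  }
  if (length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).")
  }
  x <- as.numeric(new_auc_delta)
  pred <- model$intercept + model$slope * x
  se <- model$residual_sd *
    sqrt(1 + 1 / model$n + (x - model$x_mean)^2 / model$x_ssx)
  tcrit <- qt(1 - (1 - level) / 2, df = model$df)
  extrap <- x < model$x_range[1L] | x > model$x_range[2L]
  if (any(extrap)) {
    warn(sprintf(
      "%d prediction(s) outside the fitted AUC-delta range [%.3g, %.3g]; predictions there may be less accurate.",
      sum(extrap), model$x_range[1L], model$x_range[2L]
    ))
  }
  tibble(
    auc_delta = x,
    predicted_loss_log10 = pred,
    lower = pred - tcrit * se,
    upper = pred + tcrit * se,
    level = level,
    extrapolated = extrap
  )
}

#' Wald-Wolfowitz runs test for departure from linearity
#'
#' Tests whether the residuals of a linear calibration, ordered by AUC-delta,
#' show too few (systematic curvature) or too many (over-alternation) sign
#' runs to be consistent with a linear mean. Uses the exact runs distribution
#' for n <= 30 residuals and the normal approximation (with continuity
#' correction) above; residuals that are exactly zero are dropped. If all
#' residuals are zero (a perfect fit) the test is vacuous and p = 1 is
#' returned with a note.
#'
#' @param model A `dls_linear` from [fit_linear()].
#' @param pairs Optional pairs tibble to evaluate on; defaults to the model's
#'   training data.
#' @return One-row tibble (`runs`, `n_pos`, `n_neg`, `p_value`, `method`,
#'   `note`).
#' @export
runs_test_linearity <- function(model, pairs = NULL) {
  if (!inherits(model, "dls_linear")) {
    abort("`model` must be a fitted dls_linear calibration.")
  }
  if (is.null(pairs)) pairs <- model$pairs
  if (is.null(pairs)) abort("No pairs available; supply `pairs`.")
  pairs <- validate_pairs(pairs)
  if (nrow(pairs) < 4) abort("Runs test needs at least 4 observations.")
  ord <- order(pairs$auc_delta)
  res <- pairs$titer_loss_log10[ord] -
    (model$intercept + model$slope * pairs$auc_delta[ord])
  signs <- sign(res)[abs(res) > 1e-12] # zero residuals dropped
  if (length(signs) == 0) {
    return(tibble(runs = NA_integer_, n_pos = 0L, n_neg = 0L, p_value = 1,
                  method = "degenerate",
                  note = "all residuals zero; perfect linear fit"))
  }
  n_pos <- sum(signs > 0)
  n_neg <- sum(signs < 0)
  runs <- 1L + sum(signs[-1L] != signs[-length(signs)])
  if (n_pos == 0 || n_neg == 0) {
    return(tibble(runs = runs, n_pos = n_pos, n_neg = n_neg, p_value = 1,
                  method = "degenerate",
                  note = "residuals all of one sign"))
  }
  n <- n_pos + n_neg
  if (n <= 30) {
    pmf <- runs_pmf(n_pos, n_neg)
    p_low <- sum(pmf[seq_len(runs - 1L)])           # P(R < r)
    p_le <- p_low + pmf[runs]                       # P(R <= r)
    p_ge <- 1 - p_low                               # P(R >= r)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- 1 + 2 * n_pos * n_neg / n
    v <- 2 * n_pos * n_neg * (2 * n_pos * n_neg - n) / (n^2 * (n - 1))
    z <- (runs - mu + 0.5 * sign(mu - runs)) / sqrt(v) # continuity-corrected
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble(runs = as.integer(runs), n_pos = as.integer(n_pos),
         n_neg = as.integer(n_neg), p_value = p, method = method,
         note = NA_character_)
}

# exact pmf of the number of runs in a random arrangement of n1 pluses and
# n2 minuses; index r of the returned vector is P(R = r), r = 1..n1+n2
runs_pmf <- function(n1, n2) {
  n <- n1 + n2
  total <- choose(n, n1)
  pmf <- numeric(n)
  for (r in 2:n) {
    if (r %% 2 == 0) {
      k <- r / 2
      pmf[r] <- 2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / total
    } else {
      k <- (r - 1) / 2
      pmf[r] <- (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
                   choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / total
    }
  }
  pmf
}
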
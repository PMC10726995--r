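test_that("linear calibration reproduces exact collinear data and enforces contracts", {
  pairs <- tibble::tibble(auc_delta = c(0, 10, 20),
                          titer_loss_log10 = c(0, 1, 2))
  fit <- suppressWarnings(fit_linear(pairs))
  expect_equal(fit$slope, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, fit$r^2, tolerance = 1e-12)

  expect_error(fit_linear(pairs[1:2, ]), "at least 3")
  expect_error(
    fit_linear(tibble::tibble(auc_delta = c(5, 5, 5),
                              titer_loss_log10 = c(1, 2, 3))),
    "no variation in predictor"
  )
})

test_that("OLS coefficients match the closed-form normal equations", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    pairs <- tibble::tibble(
      auc_delta = runif(n, 0, 180),
      titer_loss_log10 = rnorm(n, 2, 1.5)
    )
    fit <- fit_linear(pairs)
    X <- cbind(1, pairs$auc_delta)
    beta <- solve(t(X) %*% X, t(X) %*% pairs$titer_loss_log10)
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
    res <- pairs$titer_loss_log10 - X %*% beta
    expect_equal(fit$residual_sd, sqrt(sum(res^2) / (n - 2)),
                 tolerance = 1e-10)
  }
})

test_that("Pearson p-value agrees with a permutation test", {
  set.seed(77)
  pairs <- tibble::tibble(
    auc_delta = runif(20, 0, 150),
    titer_loss_log10 = NA
  )
  pairs$titer_loss_log10 <- 0.01 * pairs$auc_delta + rnorm(20, 0, 0.8)
  fit <- fit_linear(pairs)
  r_obs <- abs(fit$r)
  B <- 10000
  r_perm <- replicate(B, abs(cor(pairs$auc_delta,
                                 sample(pairs$titer_loss_log10))))
  p_perm <- (1 + sum(r_perm >= r_obs)) / (B + 1)
  mc_se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(fit$p_value - p_perm), 4 * mc_se + 0.002)
})

test_that("calibration is equivariant under shifts of loss and scalings of AUC-delta", {
  set.seed(5)
  pairs <- tibble::tibble(auc_delta = runif(30, 0, 150),
                          titer_loss_log10 = rnorm(30, 3, 1))
  f0 <- fit_linear(pairs)
  f_shift <- fit_linear(dplyr::mutate(pairs,
                                      titer_loss_log10 = titer_loss_log10 + 2))
  expect_equal(f_shift$slope, f0$slope, tolerance = 1e-10)
  expect_equal(f_shift$intercept, f0$intercept + 2, tolerance = 1e-10)
  f_scale <- fit_linear(dplyr::mutate(pairs, auc_delta = auc_delta / 2))
  expect_equal(f_scale$slope, f0$slope * 2, tolerance = 1e-10)
  expect_equal(f_scale$r_squared, f0$r_squared, tolerance = 1e-10)
})

test_that("tidy and glance expose the inference summaries", {
  set.seed(8)
  pairs <- tibble::tibble(auc_delta = runif(15, 0, 100),
                          titer_loss_log10 = rnorm(15, 1, 1))
  fit <- fit_linear(pairs)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "auc_delta"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_equal(gl$nobs, 15L)
  # slope t-test p equals the Pearson correlation p for simple regression
  expect_equal(td$p.value[2], fit$p_value, tolerance = 1e-10)
})

test_that("prediction intervals behave like regression prediction intervals", {
  exact <- suppressWarnings(fit_linear(
    tibble::tibble(auc_delta = c(0, 10, 20), titer_loss_log10 = c(0, 1, 2))
  ))
  p <- predict_titer_loss(exact, 10)
  expect_equal(p$predicted_loss_log10, 1, tolerance = 1e-9)
  expect_lt(p$upper - p$lower, 1e-6) # exact fit: zero-width interval

  set.seed(9)
  pairs <- tibble::tibble(auc_delta = runif(40, 10, 150),
                          titer_loss_log10 = NA)
  pairs$titer_loss_log10 <- 0.04 * pairs$auc_delta + rnorm(40, 0, 0.5)
  fit <- fit_linear(pairs)
  xs <- seq(ceiling(fit$x_range[1]), floor(fit$x_range[2]), by = 5)
  w <- predict_titer_loss(fit, xs)$upper - predict_titer_loss(fit, xs)$lower
  expect_equal(xs[which.min(w)], xs[which.min(abs(xs - fit$x_mean))])

  # matches stats::predict.lm on the training lm
  ref <- predict(fit$lm, newdata = data.frame(auc_delta = c(30, 90)),
                 interval = "prediction", level = 0.95)
  got <- predict_titer_loss(fit, c(30, 90))
  expect_equal(got$predicted_loss_log10, unname(ref[, "fit"]),
               tolerance = 1e-10)
  expect_equal(got$lower, unname(ref[, "lwr"]), tolerance = 1e-10)
  expect_equal(got$upper, unname(ref[, "upr"]), tolerance = 1e-10)

  expect_warning(predict_titer_loss(fit, 199), "outside")
  expect_error(predict_titer_loss(fit, 300), "within")
})

test_that("seeded parameter-recovery: slope found within its own CI, prediction near truth", {
  # loss = 0.05 * AUC-delta + N(0, 0.3)
  hits <- 0
  preds <- numeric(50)
  for (s in 1:50) {
    set.seed(1000 + s)
    x <- runif(50, 0, 180)
    pairs <- tibble::tibble(auc_delta = x,
                            titer_loss_log10 = 0.05 * x + rnorm(50, 0, 0.3))
    fit <- fit_linear(pairs)
    se <- fit$coef_table[2, 2]
    ci <- fit$slope + c(-1, 1) * qt(0.975, fit$df) * se
    if (ci[1] <= 0.05 && 0.05 <= ci[2]) hits <- hits + 1
    preds[s] <- predict_titer_loss(fit, 100)$predicted_loss_log10
  }
  expect_gte(hits / 50, 0.9)
  expect_lt(max(abs(preds - 5.0)), 0.2)
})

test_that("runs test uses the exact runs distribution and flags the degenerate fit", {
  # strictly alternating signs, n = 10: two-sided exact p = 2 * 2/252
  pairs <- tibble::tibble(
    auc_delta = seq(10, 100, by = 10),
    titer_loss_log10 = rep(c(0.1, -0.1), 5)
  )
  flat <- fit_linear(pairs)
  # force the zero line so residuals are the alternating values themselves
  flat$slope <- 0; flat$intercept <- 0
  rt <- runs_test_linearity(flat, pairs)
  expect_equal(rt$runs, 10L)
  expect_equal(rt$p_value, 2 * (2 / choose(10, 5)), tolerance = 1e-12)
  expect_lt(rt$p_value, 0.05)

  # 2 runs: + + + + + - - - - -
  pairs2 <- tibble::tibble(
    auc_delta = seq(10, 100, by = 10),
    titer_loss_log10 = c(rep(0.1, 5), rep(-0.1, 5))
  )
  m2 <- fit_linear(pairs2)
  m2$slope <- 0; m2$intercept <- 0
  rt2 <- runs_test_linearity(m2, pairs2)
  expect_equal(rt2$runs, 2L)
  # P(R <= 2) = P(R = 2) = 2/252; two-sided doubles the smaller tail
  expect_equal(rt2$p_value, 2 * (2 / choose(10, 5)), tolerance = 1e-12)

  # perfectly linear data: all residuals zero -> vacuous test, p = 1
  lin <- suppressWarnings(fit_linear(
    tibble::tibble(auc_delta = c(0, 10, 20, 30),
                   titer_loss_log10 = c(0, 1, 2, 3))
  ))
  rt3 <- runs_test_linearity(lin)
  expect_equal(rt3$p_value, 1)
  expect_match(rt3$note, "perfect linear fit")

  # n > 30 switches to the normal approximation
  set.seed(12)
  big <- tibble::tibble(auc_delta = sort(runif(40, 0, 180)),
                        titer_loss_log10 = rnorm(40))
  rtb <- runs_test_linearity(fit_linear(big))
  expect_equal(rtb$method, "normal approximation")
  expect_gt(rtb$p_value, 0)
  expect_lte(rtb$p_value, 1)
})

test_that("exact runs pmf sums to one and matches enumeration at small n", {
  pmf <- dlsqc:::runs_pmf(4, 3)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # enumeration oracle over all C(7,4) = 35 arrangements
  combs <- utils::combn(7, 4)
  counts <- integer(7)
  for (j in seq_len(ncol(combs))) {
    s <- rep(-1, 7); s[combs[, j]] <- 1
    r <- 1 + sum(s[-1] != s[-7])
    counts[r] <- counts[r] + 1
  }
  expect_equal(pmf, counts / 35, tolerance = 1e-12)
})

test_that("logistic classifier: null data give flat odds and chance ROC", {
  set.seed(21)
  pairs <- tibble::tibble(
    auc_delta = runif(400, 0, 200),
    titer_loss_log10 = sample(c(0, 2), 400, replace = TRUE)
  )
  fit <- fit_logistic(pairs, 1)
  expect_lt(abs(fit$or_pct_per_unit), 1)
  expect_lt(abs(fit$roc_auc - 0.5), 0.08)
  expect_lt(fit$tjur_r2, 0.05)
  expect_false(fit$separation)
  expect_true(fit$or_ci95[1] <= fit$or_pct_per_unit &&
                fit$or_pct_per_unit <= fit$or_ci95[2])
})

test_that("Tjur R-squared is 1 for a perfectly discriminated toy set and separation is flagged", {
  pairs <- tibble::tibble(
    auc_delta = c(10, 20, 30, 40, 110, 120, 130, 140),
    titer_loss_log10 = c(0, 0, 0, 0, 2, 2, 2, 2)
  )
  expect_warning(fit <- fit_logistic(pairs, 1), "separation")
  expect_true(fit$separation)
  expect_equal(fit$tjur_r2, 1, tolerance = 1e-4)
  expect_equal(fit$roc_auc, 1)

  # oracle grid search: likelihood increases monotonically in beta1 along the
  # MLE path, confirming the divergence the flag reports
  loglik <- function(b1) {
    b0 <- -b1 * 75 # separating midpoint
    p <- plogis(b0 + b1 * pairs$auc_delta)
    y <- as.integer(pairs$titer_loss_log10 > 1)
    sum(log(ifelse(y == 1, p, 1 - p)))
  }
  lls <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), loglik, numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("degenerate one-class outcomes are rejected", {
  pairs <- tibble::tibble(auc_delta = c(1, 2, 3, 4),
                          titer_loss_log10 = c(0.1, 0.2, 0.1, 0.3))
  expect_error(fit_logistic(pairs, 1), "degenerate outcome")
})

test_that("ROC curve area equals the Mann-Whitney statistic, ties included", {
  # 4 scores with one tie, labels (1,1,0,0)
  y <- c(1, 1, 0, 0)
  score <- c(0.9, 0.5, 0.5, 0.1)
  auc_rank <- dlsqc:::rank_roc_auc(y, score)
  # brute force over all positive-negative pairs
  brute <- mean(outer(score[y == 1], score[y == 0],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc_rank, brute, tolerance = 1e-12)
  expect_equal(auc_rank, 0.875)

  set.seed(31)
  pairs <- tibble::tibble(
    auc_delta = round(runif(60, 0, 200) / 10) * 10, # force ties
    titer_loss_log10 = NA
  )
  pairs$titer_loss_log10 <- ifelse(
    plogis(-3 + 0.04 * pairs$auc_delta) > runif(60), 2, 0
  )
  fit <- fit_logistic(pairs, 1)
  brute2 <- mean(outer(fit$fitted_prob[fit$outcome == 1],
                       fit$fitted_prob[fit$outcome == 0],
                       function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(fit$roc_auc, brute2, tolerance = 1e-12)
  roc <- roc_curve(fit)
  expect_equal(dlsqc:::roc_trapezoid_area(roc), fit$roc_auc,
               tolerance = 1e-9)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("ROC-AUC of random scores with balanced classes is near 1/2", {
  set.seed(99)
  y <- rep(c(0, 1), 1000)
  score <- runif(2000)
  expect_lt(abs(dlsqc:::rank_roc_auc(y, score) - 0.5), 0.04)
})

test_that("threshold sweep reports feasible thresholds and skips empty classes", {
  set.seed(17)
  sim <- simulate_decay(decay_config(seed = 17), 60, 3)
  pairs <- sim_pairs(sim)
  sw <- suppressWarnings(threshold_sweep(pairs))
  expect_equal(sw$threshold_log10, c(0.5, 1, 1.5, 2, 2.5, 3))
  expect_false(any(sw$skipped))

  single <- suppressWarnings(threshold_sweep(pairs, thresholds = 1))
  ref <- suppressWarnings(fit_logistic(pairs, 1))
  expect_equal(single$or_pct_per_unit, ref$or_pct_per_unit)
  expect_equal(single$roc_auc, ref$roc_auc)

  tiny <- tibble::tibble(auc_delta = c(1, 5, 9, 12),
                         titer_loss_log10 = c(0.1, 0.2, 0.3, 0.4))
  sw2 <- threshold_sweep(tiny)
  expect_true(all(sw2$skipped)) # no losses above any threshold
  expect_error(threshold_sweep(tiny, thresholds = numeric(0)), "non-empty")
})

test_that("rank ROC-AUC and Wald inference agree with independent references", {
  skip_if_not_installed("pROC")
  set.seed(55)
  pairs <- tibble::tibble(auc_delta = runif(120, 0, 200),
                          titer_loss_log10 = NA)
  pairs$titer_loss_log10 <- ifelse(
    plogis(-2 + 0.03 * pairs$auc_delta) > runif(120), 3, 0
  )
  fit <- fit_logistic(pairs, 1)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = fit$outcome, predictor = fit$fitted_prob, quiet = TRUE
  )))
  expect_equal(fit$roc_auc, as.numeric(ref), tolerance = 1e-12)

  # Tjur R2 is shuffle-null: near zero under label permutation
  set.seed(56)
  shuf <- pairs
  shuf$titer_loss_log10 <- sample(shuf$titer_loss_log10)
  expect_lt(abs(fit_logistic(shuf, 1)$tjur_r2), 0.1)
})
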
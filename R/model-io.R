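#' Serialize and restore fitted calibrations as JSON
#'
#' Fitted linear and logistic calibrations round-trip through a small
#' versioned JSON schema so that a model trained once (e.g. via the `train`
#' command) can be applied to new spectra later. Restored models support
#' [predict_titer_loss()] / probability prediction, [generics::glance()] and
#' printing; they do not carry the training data, so data-dependent
#' diagnostics ([runs_test_linearity()], [roc_curve()]) need the original
#' pairs.
#'
#' @param model A `dls_linear` or `dls_logistic`.
#' @param path Output JSON path.
#' @return `write_model_json()`: `path` invisibly. `read_model_json()`: the
#'   restored model object.
#' @export
write_model_json <- function(model, path) {
  if (inherits(model, "dls_linear")) {
    obj <- list(
      schema_version = 1L, type = "linear",
      slope = model$slope, intercept = model$intercept,
      r = model$r, r_squared = model$r_squared, p_value = model$p_value,
      n = model$n, residual_sd = model$residual_sd, df = model$df,
      x_mean = model$x_mean, x_ssx = model$x_ssx, x_range = model$x_range,
      coef_table = coef_table_to_list(model$coef_table)
    )
  } else if (inherits(model, "dls_logistic")) {
    obj <- list(
      schema_version = 1L, type = "logistic",
      threshold_log10 = model$threshold_log10,
      beta0 = model$beta0, beta1 = model$beta1, se_beta1 = model$se_beta1,
      or_pct_per_unit = model$or_pct_per_unit, or_ci95 = model$or_ci95,
      p_value = model$p_value, tjur_r2 = model$tjur_r2,
      roc_auc = model$roc_auc, n = model$n, n_pos = model$n_pos,
      separation = model$separation, x_range = model$x_range
    )
  } else {
    abort("`model` must be a dls_linear or dls_logistic.")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

coef_table_to_list <- function(ct) {
  list(term = rownames(ct), estimate = unname(ct[, 1L]),
       std_error = unname(ct[, 2L]), statistic = unname(ct[, 3L]),
       p_value = unname(ct[, 4L]))
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1) {
    abort("Unsupported model schema version.")
  }
  if (identical(obj$type, "linear")) {
    ct <- with(obj$coef_table, {
      m <- cbind(estimate, std_error, statistic, p_value)
      rownames(m) <- term
      colnames(m) <- c("Estimate", "Std. Error", "t value", "Pr(>|t|)")
      m
    })
    structure(
      list(slope = obj$slope, intercept = obj$intercept, r = obj$r,
           r_squared = obj$r_squared, p_value = obj$p_value, n = obj$n,
           residual_sd = obj$residual_sd, df = obj$df, x_mean = obj$x_mean,
           x_ssx = obj$x_ssx, x_range = obj$x_range, coef_table = ct,
           pairs = NULL, lm = NULL),
      class = "dls_linear"
    )
  } else if (identical(obj$type, "logistic")) {
    structure(
      list(threshold_log10 = obj$threshold_log10, beta0 = obj$beta0,
           beta1 = obj$beta1, se_beta1 = obj$se_beta1,
           or_pct_per_unit = obj$or_pct_per_unit, or_ci95 = obj$or_ci95,
           p_value = obj$p_value, tjur_r2 = obj$tjur_r2,
           roc_auc = obj$roc_auc, n = obj$n, n_pos = obj$n_pos,
           separation = obj$separation, x_range = obj$x_range,
           fitted_prob = NULL, outcome = NULL, pairs = NULL, glm = NULL),
      class = "dls_logistic"
    )
  } else {
    abort(sprintf("Unknown model type '%s'.", obj$type))
  }
}

#' Read and write paired (AUC-delta, titer loss) observations
#'
#' Long-format CSV with columns `auc_delta` and `titer_loss_log10`; optional
#' `phage_id`, `condition`, `sample` and `censored` columns are preserved
#' (missing `censored` defaults to FALSE).
#'
#' @param path CSV path.
#' @return Pairs tibble suitable for [fit_linear()] and [fit_logistic()].
#' @export
read_pairs_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  pairs <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  validate_pairs(pairs)
}

#' @rdname read_pairs_csv
#' @param pairs Pairs tibble.
#' @export
write_pairs_csv <- function(pairs, path) {
  pairs <- validate_pairs(pairs)
  readr::write_csv(pairs, path, progress = FALSE)
  invisible(path)
}
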
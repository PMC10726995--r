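#' Plot DLS size-intensity spectra
#'
#' Overlays spectra on a log10 diameter axis, one colored line per sample —
#' the standard way DLS exports are inspected for fragment and aggregate
#' peaks.
#'
#' @param spectra Spectra tibble (`sample`, `size_nm`, `intensity`).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra) {
  validate_spectra(spectra)
  ggplot2::ggplot(spectra, ggplot2::aes(x = .data$size_nm, y = .data$intensity,
                                        color = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hydrodynamic diameter (nm)",
                  y = "Relative intensity (%)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Calibration scatter with fitted line and prediction band
#'
#' @param object A `dls_linear` fitted by [fit_linear()] (must carry its
#'   training data).
#' @param level Prediction-interval coverage for the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dls_linear <- function(object, level = 0.95, ...) {
  if (is.null(object$pairs)) {
    abort("Model carries no training data; plot from the original fit.")
  }
  xs <- seq(object$x_range[1L], object$x_range[2L], length.out = 100)
  band <- predict_titer_loss(object, xs, level = level)
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$auc_delta,
                               y = .data$titer_loss_log10)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$auc_delta, ymin = .data$lower,
                   ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.15
    ) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "AUC-delta", y = "Titer loss (log10 PFU/mL)",
      subtitle = sprintf("r^2 = %.2f, p = %.2g, n = %d",
                         object$r_squared, object$p_value, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve of a threshold classifier
#'
#' @param object A `dls_logistic` fitted by [fit_logistic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dls_logistic <- function(object, ...) {
  if (is.null(object$fitted_prob)) {
    abort("Model carries no fitted probabilities; plot from the original fit.")
  }
  roc <- roc_curve(object)
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      subtitle = sprintf("> %g log10 loss: ROC-AUC = %.2f, Tjur R^2 = %.2f",
                         object$threshold_log10, object$roc_auc,
                         object$tjur_r2)
    ) +
    ggplot2::theme_minimal()
}
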
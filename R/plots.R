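#' Plot the threshold sweep
#'
#' Nagelkerke R-squared of the score term against the p-value inclusion
#' threshold, with the selected threshold marked.
#'
#' @param object A `prs_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prs_profile
#' @export
autoplot.prs_profile <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$p_T, y = .data$r2)) +
    ggplot2::geom_line(colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$best_p_T,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "p-value threshold (log scale)",
                  y = "Nagelkerke R² of PRS term",
                  title = sprintf("Best p_T = %g (R² = %.3f)",
                                  object$best_p_T, object$best_r2)) +
    ggplot2::theme_minimal()
}

#' ROC curve of a fitted conversion model
#'
#' @param fit A `neuroprs_logistic` fit.
#' @return A ggplot of the empirical ROC with the AUC in the title.
#' @export
plot_roc <- function(fit) {
  stopifnot(inherits(fit, "neuroprs_logistic"))
  pts <- roc_points(fit$linear_predictors, fit$y)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", fit$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a brain-region association scan
#'
#' Signed partial correlations ordered by p-value, coloured by measure
#' type, with FDR-significant tests highlighted.
#'
#' @param object A `region_scan` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot region_scan
#' @export
autoplot.region_scan <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$r,
                                   colour = .data$measure,
                                   shape = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 17)) +
    ggplot2::labs(x = "Region-measure tests (ordered by p)",
                  y = "Partial correlation with PRS",
                  shape = "q < 0.05") +
    ggplot2::theme_minimal()
}

#' Cumulative conversion-risk curves
#'
#' @param cox A `neuroprs_cox` fit.
#' @param newdata Covariate profiles (one curve each).
#' @param times Evaluation times (default: baseline event times).
#' @param labels Optional labels for the profiles.
#' @return A ggplot of `1 - exp(-Lambda0(t) exp(x beta))` per profile.
#' @export
plot_cumulative_risk <- function(cox, newdata, times = NULL,
                                 labels = NULL) {
  risk <- cumulative_risk(cox, newdata, times)
  if (!is.null(labels)) {
    risk$profile <- factor(labels[risk$profile], levels = unique(labels))
  } else {
    risk$profile <- factor(risk$profile)
  }
  ggplot2::ggplot(risk, ggplot2::aes(x = .data$time, y = .data$risk,
                                     colour = .data$profile)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years of follow-up", y = "Cumulative conversion risk",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
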
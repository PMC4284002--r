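# ggplot2 visualisations for the main result types.

#' Manhattan plot of a GWAS result
#'
#' @param object A `gwas_result`.
#' @param threshold Optional horizontal reference line (p-value scale),
#'   e.g. a Bonferroni threshold.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gwas_result <- function(object, threshold = NULL, ...) {
  d <- dplyr::filter(tidy(object), !is.na(.data$p_value))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos,
                                       y = -log10(.data$p_value),
                                       colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position", y = expression(-log[10](italic(p))),
                  title = sprintf("%s scan (lambda[GC] = %.2f)",
                                  object$method, object$lambda_gc)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  }
  p
}

#' Quantile-quantile plot of GWAS p-values
#'
#' Observed versus expected -log10 p under the uniform null; the departure
#' of the bulk from the diagonal visualises confounding (inflation factor
#' in the subtitle).
#'
#' @param object A `gwas_result`.
#' @return A ggplot object.
#' @export
plot_gwas_qq <- function(object) {
  p <- sort(stats::na.omit(tidy(object)$p_value))
  d <- tibble::tibble(expected = -log10(stats::ppoints(length(p))),
                      observed = -log10(p))
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = expression(expected ~ -log[10](italic(p))),
                  y = expression(observed ~ -log[10](italic(p))),
                  subtitle = sprintf("lambda[GC] = %.3f", object$lambda_gc)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of PCA scores
#'
#' @param object A `pca_result`.
#' @param axes Two axes to display.
#' @param labels Optional named group labels (e.g. subpopulations).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_result <- function(object, axes = c(1, 2), labels = NULL, ...) {
  d <- tidy(object)
  xs <- paste0("PC", axes)
  if (!is.null(labels)) d$group <- labels[d$id]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[xs[1]]], .data[[xs[2]]]))
  p <- if (is.null(labels)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  p + ggplot2::labs(
    x = sprintf("%s (%.1f%%)", xs[1], object$pct_variance[axes[1]]),
    y = sprintf("%s (%.1f%%)", xs[2], object$pct_variance[axes[2]])) +
    ggplot2::theme_minimal()
}

#' Power and naive-PVE inflation curve
#'
#' @param object A `power_curve`.
#' @param ... Unused.
#' @return A ggplot object with power and mean naive PVE against the
#'   expected PVE grid.
#' @export
autoplot.power_curve <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(object$curve, "expected_pve", "power", "mean_naive_pve"),
    -"expected_pve", names_to = "measure")
  ggplot2::ggplot(d, ggplot2::aes(.data$expected_pve, .data$value,
                                  colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "expected PVE", y = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution of per-repeat predictive ability
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "predictive ability r", y = "repeats") +
    ggplot2::theme_minimal()
}
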
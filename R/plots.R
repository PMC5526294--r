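#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_tile
#'   geom_point geom_histogram annotate labs scale_fill_gradient
#'   coord_equal theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object a [roc_auc()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(linewidth = 0.8) +
    coord_equal() +
    labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC: AUC %.2f (%d%% CI %.2f-%.2f)", object$auc,
                      round(100 * object$level), object$ci[1], object$ci[2])
    ) +
    theme_minimal()
}

#' Heatmap of grid-search performance
#'
#' Median CV AUC per feature-selection method x classifier family,
#' maximized over the remaining grid coordinates.
#'
#' @param object a [run_grid()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.grid_result <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$fs_method, .data$classifier),
    auc = max(.data$summary_auc, na.rm = TRUE), .groups = "drop"
  )
  ggplot(df, aes(x = .data$fs_method, y = .data$classifier,
                 fill = .data$auc)) +
    geom_tile() +
    scale_fill_gradient(low = "grey90", high = "grey20", name = "AUC") +
    labs(x = "Feature selection", y = "Classifier",
         title = "Best median CV AUC per method pair") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Score distribution with the indeterminate window
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param range an [optimize_range()] result.
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_indeterminate <- function(scores, labels, range, bins = 40) {
  stopifnot(inherits(range, "indeterminate_range"))
  df <- tibble(score = scores, label = as.character(labels))
  p <- ggplot(df, aes(x = .data$score)) +
    geom_histogram(bins = bins, fill = "grey70", colour = "white") +
    facet_wrap(~label, ncol = 1, scales = "free_y") +
    labs(x = "Classifier score", y = "Subjects",
         title = sprintf("Indeterminate window [%.3g, %.3g] (%.0f%% of optimization set)",
                         range$lo, range$hi, 100 * range$fraction)) +
    theme_minimal()
  if (range$feasible) {
    p <- p + annotate("rect", xmin = range$lo, xmax = range$hi,
                      ymin = -Inf, ymax = Inf, alpha = 0.25, fill = "orange")
  }
  p
}

#' Plot a fitted 4PL standard curve over its standards
#'
#' @param curve a [fit_standard_curve()] result.
#' @param n_grid evaluation points.
#' @return a ggplot.
#' @export
plot_standard_curve <- function(curve, n_grid = 200) {
  stopifnot(inherits(curve, "standard_curve"))
  std <- curve$standards
  pos <- std$concentration[std$concentration > 0]
  xs <- exp(seq(log(min(pos) / 4), log(max(pos) * 2), length.out = n_grid))
  fitdf <- tibble(concentration = xs,
                  response = fourpl(xs, curve$a, curve$d, curve$c, curve$b))
  ggplot(std, aes(x = .data$concentration, y = .data$response)) +
    geom_line(data = fitdf, colour = "steelblue") +
    geom_point() +
    ggplot2::scale_x_log10() +
    labs(x = "Concentration (diluted, pg/mL)", y = "Response (ECL)",
         title = sprintf("4PL fit: b = %.2f, weighted R² = %.4f",
                         curve$b, curve$r_squared)) +
    theme_minimal()
}
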
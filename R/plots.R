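# ggplot2 autoplot() methods for the workflow's result objects.

#' Elbow plot of a k-means scan
#'
#' @param object A `cluster_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$k, y = .data$distortion)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "number of clusters k",
                  y = "distortion (mean squared distance)",
                  title = "Elbow plot of descriptor-space clustering") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-observed plot of a model report
#'
#' Training records in black, held-out catalysts in red, on the free-energy
#' scale.
#'
#' @param object A `model_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               colour = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(train = "black", test = "red")) +
    ggplot2::labs(x = expression(observed ~ Delta * Delta * G ~ "(kcal/mol)"),
                  y = expression(predicted ~ Delta * Delta * G ~ "(kcal/mol)")) +
    ggplot2::theme_minimal()
}

#' Best-so-far trace of an optimization campaign
#'
#' @param object A `campaign_state`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.campaign_state <- function(object, ...) {
  ggplot2::ggplot(object$best_trace,
                  ggplot2::aes(x = .data$round, y = 100 * .data$best_abs_ee)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "round (0 = initial training set)",
                  y = "best |ee| so far (%)",
                  title = "Campaign best-so-far selectivity") +
    ggplot2::theme_minimal()
}

#' Histogram of a selectivity distribution with its normal fit
#'
#' @param values Numeric selectivity values (ee or DDG scale).
#' @param bins Histogram bin count.
#' @return A ggplot annotated with skewness/kurtosis and the KS p-value.
#' @export
plot_selectivity_distribution <- function(values, bins = 20) {
  s <- summarize_distribution(values)
  df <- tibble::tibble(value = values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", colour = "white") +
    ggplot2::stat_function(fun = stats::dnorm,
                           args = list(mean = s$mean, sd = s$sd),
                           colour = "red") +
    ggplot2::labs(
      x = "selectivity",
      y = "density",
      subtitle = sprintf("skew = %.2f, excess kurtosis = %.2f, KS p = %.3f",
                         s$skewness, s$excess_kurtosis, s$ks_p_value)
    ) +
    ggplot2::theme_minimal()
}
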
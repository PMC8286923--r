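# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an embedding
#'
#' Scatter of the first two embedding coordinates.
#'
#' @param object An `"fcn_embedding"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fcn_embedding <- function(object, ...) {
  df <- tidy(object)
  if (!"dim2" %in% names(df)) df$dim2 <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s embedding", object$method),
      x = "dimension 1", y = "dimension 2"
    )
}

#' Plot per-repeat cross-validation accuracies
#'
#' @param object An `"fcn_cv"`.
#' @param ... Unused.
#' @return A ggplot histogram of per-repeat accuracies with the mean
#'   marked.
#' @export
autoplot.fcn_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_accuracy, linetype = 2) +
    ggplot2::labs(
      x = "accuracy per repeat (%)", y = "repeats",
      title = sprintf("%s: %.1f%% +/- %.1f%%", object$classifier,
                      object$mean_accuracy, object$sd_accuracy)
    )
}

#' Plot sweep accuracies across the threshold grid
#'
#' One line per method, faceted by metric, best points marked.
#'
#' @param object An `"fcn_sweep"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fcn_sweep <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pt, y = .data$accuracy,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$best), shape = 8) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "proportional threshold", y = "mean accuracy (%)")
}

#' Plot the heat-kernel scale selection curve
#'
#' Median sum of weights against `sigma` (log scale) with the selected
#' scale and its linear region marked.
#'
#' @param object A `"sigma_selection"` from [select_sigma()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sigma_selection <- function(object, ...) {
  df <- tibble::tibble(sigma = object$grid, S_w = object$median_sw)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma, y = .data$S_w)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$sigma, colour = "red", linetype = 2) +
    ggplot2::geom_vline(xintercept = object$region, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(sigma), y = "median sum of weights")
}
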
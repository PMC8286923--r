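# broom-style tidy()/glance() methods for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a RAICAR result
#'
#' @param x A [raicar()] result.
#' @param ... Unused.
#' @return A tibble with one row per aligned component in rank order:
#'   `rank`, `group` (original group index), `index` (reproducibility),
#'   `selected`, `flagged`.
#' @export
tidy.raicar_result <- function(x, ...) {
  tibble::tibble(
    rank = seq_along(x$index),
    group = x$order,
    index = x$index,
    selected = x$selected,
    flagged = x$flagged
  )
}

#' @rdname tidy.raicar_result
#' @return `glance()` returns a one-row tibble: `K`, `M`, `threshold`,
#'   `cutoff`, `n_selected`, `included`.
#' @export
glance.raicar_result <- function(x, ...) {
  tibble::tibble(
    K = x$K, M = x$M, threshold = x$threshold, cutoff = x$cutoff,
    n_selected = x$n_selected, included = x$included
  )
}

#' Tidy an embedding
#'
#' @param x An `"fcn_embedding"`.
#' @param ... Unused.
#' @return A tibble with `component`, one column per embedding dimension
#'   (`dim1`, `dim2`, ...).
#' @export
tidy.fcn_embedding <- function(x, ...) {
  co <- x$coordinates
  out <- tibble::as_tibble(co, .name_repair = ~ paste0("dim", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(component = rownames(co) %||% as.character(seq_len(nrow(co)))),
    out
  )
}

#' @rdname tidy.fcn_embedding
#' @export
glance.fcn_embedding <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    p = ncol(x$coordinates),
    n_points = nrow(x$coordinates),
    leading_eigenvalue = if (x$ascending) min(x$eigenvalues) else max(x$eigenvalues)
  )
}

#' Tidy a cross-validation result
#'
#' @param x An `"fcn_cv"` from [repeated_kfold_cv()].
#' @param ... Unused.
#' @return One row per repeat: `repeat_id`, `accuracy` (percent).
#' @export
tidy.fcn_cv <- function(x, ...) {
  tibble::tibble(repeat_id = seq_along(x$accuracies), accuracy = x$accuracies)
}

#' @rdname tidy.fcn_cv
#' @export
glance.fcn_cv <- function(x, ...) {
  tibble::tibble(
    classifier = x$classifier, folds = x$folds, repeats = x$repeats,
    n = x$n, mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy,
    sensitivity = x$sensitivity, specificity = x$specificity
  )
}

#' Tidy a sweep result
#'
#' @param x An `"fcn_sweep"` from [sweep_configurations()].
#' @param ... Unused.
#' @return `tidy()` returns the full results tibble; `glance()` the best
#'   row per method x metric.
#' @export
tidy.fcn_sweep <- function(x, ...) x$results

#' @rdname tidy.fcn_sweep
#' @export
glance.fcn_sweep <- function(x, ...) {
  dplyr::select(dplyr::filter(x$results, .data$best), -"best")
}
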
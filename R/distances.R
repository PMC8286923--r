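#' Normalized cross-correlation of two time series at a given lag
#'
#' The estimator averages the lagged cross-products over the `T - l`
#' overlapping samples and normalizes by the full-series standard
#' deviations (population form, i.e. second moments about the full-series
#' means). With finite samples the value can exceed 1 in magnitude by a
#' small amount; no clipping is applied here.
#'
#' @param a,b Numeric vectors of equal length (>= 8), nonzero variance.
#' @param l Nonnegative integer lag; `a` is advanced by `l` relative to `b`.
#' @return A single correlation value.
#' @examples
#' x <- sin(seq(0, 4 * pi, length.out = 64))
#' ccf_lag(x, x, 0)
#' @export
ccf_lag <- function(a, b, l) {
  if (length(a) != length(b)) abort_field("b", "must have the same length as `a`")
  n <- length(a)
  l <- check_count(l, "l", min = 0L)
  if (l >= n) abort_field("l", "must be smaller than the series length")
  ma <- mean(a); mb <- mean(b)
  sa <- sqrt(mean((a - ma)^2)); sb <- sqrt(mean((b - mb)^2))
  if (sa == 0 || sb == 0) abort_field("a", "zero-variance series")
  t_idx <- seq_len(n - l)
  num <- mean((a[t_idx + l] - ma) * (b[t_idx] - mb))
  num / (sa * sb)
}

#' Lag-maximized cross-correlation pseudo-distance matrix
#'
#' For every pair of component time courses computes
#' `d_c(i, j) = 1 - max_l |CCF(i, j, l)|`, the maximum taken over lags
#' `0..max_lag` in both argument orders (equivalently lags
#' `-max_lag..max_lag`), which makes the matrix symmetric. Absolute
#' correlations are clamped at 1 before the subtraction so `d_c >= 0` under
#' the finite-sample normalization.
#'
#' @param A Components x time numeric matrix.
#' @param max_lag Maximum lag considered (default 3).
#' @return A symmetric M x M matrix with zero diagonal and entries in
#'   `[0, 1]`, tagged with `attr(, "metric") == "cross_correlation"`.
#' @seealso [euclidean_distance()]
#' @export
cross_correlation_distance <- function(A, max_lag = 3L) {
  A <- check_timecourses(A, "A")
  max_lag <- check_count(max_lag, "max_lag", min = 0L)
  m <- nrow(A)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      best <- 0
      for (l in 0:max_lag) {
        best <- max(best, abs(ccf_lag(A[i, ], A[j, ], l)), abs(ccf_lag(A[j, ], A[i, ], l)))
      }
      D[i, j] <- D[j, i] <- 1 - min(best, 1)
    }
  }
  dimnames(D) <- list(rownames(A), rownames(A))
  attr(D, "metric") <- "cross_correlation"
  D
}

#' Euclidean distance matrix between component time courses
#'
#' Plain L2 distance between rows: `sqrt(sum_t (A[i, t] - A[j, t])^2)`.
#'
#' @inheritParams cross_correlation_distance
#' @return A symmetric M x M matrix with zero diagonal, tagged with
#'   `attr(, "metric") == "euclidean"`.
#' @export
euclidean_distance <- function(A) {
  A <- check_timecourses(A, "A")
  D <- as.matrix(stats::dist(A, method = "euclidean"))
  dimnames(D) <- list(rownames(A), rownames(A))
  attr(D, "metric") <- "euclidean"
  D
}
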
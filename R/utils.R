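# Internal helpers: argument validation and reproducible stream splitting.

abort_field <- function(field, msg) {
  rlang::abort(sprintf("invalid `%s`: %s", field, msg), class = "fcnembed_validation_error")
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_number <- function(x, field, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (strict_min && x <= min) abort_field(field, sprintf("must be > %g", min))
  if (!strict_min && x < min) abort_field(field, sprintf("must be >= %g", min))
  if (x > max) abort_field(field, sprintf("must be <= %g", max))
  as.numeric(x)
}

# Split one integer seed into `n` deterministic substream seeds (all < 2^31),
# so per-subject randomness is independent of cohort size ordering.
split_seed <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

check_timecourses <- function(A, field = "timecourses") {
  if (!is.matrix(A) || !is.numeric(A)) abort_field(field, "must be a numeric matrix (components x time points)")
  if (ncol(A) < 8L) abort_field(field, "needs at least 8 time points")
  v <- apply(A, 1L, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    abort_field(field, sprintf("row %d has zero or non-finite variance", which(v == 0 | !is.finite(v))[1L]))
  }
  A
}

check_distance_matrix <- function(D, field = "D") {
  if (!is.matrix(D) || !is.numeric(D)) abort_field(field, "must be a numeric matrix")
  if (nrow(D) != ncol(D)) abort_field(field, "must be square")
  if (any(!is.finite(D))) abort_field(field, "entries must be finite")
  if (any(D < -1e-12)) abort_field(field, "entries must be nonnegative")
  if (max(abs(D - t(D))) > 1e-8) abort_field(field, "must be symmetric")
  if (any(abs(diag(D)) > 1e-10)) abort_field(field, "diagonal must be zero")
  D
}

metric_tag <- function(D) attr(D, "metric") %||% "unknown"

`%||%` <- rlang::`%||%`
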
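# Reproducibility ranking of repeated ICA runs: align components across
# realizations via the cross-realization correlation matrix (CRCM), score
# each aligned group by a reproducibility index, and selectively average.

#' Cross-realization correlation matrix (CRCM)
#'
#' Stacks the spatial maps of all K realizations (M components each) and
#' computes the absolute Pearson correlation between every pair of maps,
#' giving an `(M*K) x (M*K)` symmetric matrix of K x K blocks of size
#' M x M. Diagonal blocks (within-realization correlations) are computed
#' but ignored by the alignment.
#'
#' @param stack An `"ica_stack"` (see [generate_realization_stack()]) or a
#'   list with elements `spatial_maps` (list of K matrices M x voxels), `K`,
#'   `M`.
#' @return An object of class `"crcm"`: list with `matrix`, `K`, `M`, and
#'   `block_index` (tibble mapping row -> (realization, component)).
#' @export
build_crcm <- function(stack) {
  maps <- stack$spatial_maps
  K <- length(maps); M <- nrow(maps[[1L]])
  if (K < 2L) abort_field("stack", "needs at least 2 realizations")
  shapes <- vapply(maps, function(m) paste(dim(m), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) abort_field("stack", "all map matrices must share a shape")
  if (ncol(maps[[1L]]) < 2L) abort_field("stack", "needs at least 2 voxels")
  flat <- do.call(rbind, maps)                      # (K*M) x V
  v <- apply(flat, 1L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)[1L]
    rlang::abort(sprintf(
      "zero-variance spatial map: realization %d, component %d",
      (bad - 1L) %/% M + 1L, (bad - 1L) %% M + 1L
    ), class = "fcnembed_validation_error")
  }
  R <- abs(stats::cor(t(flat)))
  structure(list(
    matrix = R, K = K, M = M,
    block_index = tibble::tibble(
      row = seq_len(K * M),
      realization = rep(seq_len(K), each = M),
      component = rep(seq_len(M), K)
    )
  ), class = "crcm")
}

# rows of the CRCM belonging to realization k
crcm_rows <- function(crcm, k) ((k - 1L) * crcm$M + 1L):(k * crcm$M)

#' Align components across realizations
#'
#' Greedy alignment: find the global maximum of the CRCM outside the
#' diagonal blocks and over still-unused components; its two endpoints seed
#' a group. In every other realization the still-unused component with the
#' highest mean absolute correlation to the two seeds joins the group. All
#' members are then marked used and the procedure repeats until M groups
#' partition all `M*K` components. Ties break on the lowest
#' (realization, component) index.
#'
#' @param crcm A [build_crcm()] result.
#' @return Integer matrix `M x K`: entry `[g, k]` is the component index of
#'   realization `k` assigned to aligned group `g`, with attribute `"seed"`
#'   (M x 2 matrix of the seed (realization, component) of each group).
#' @export
align_components <- function(crcm) {
  K <- crcm$K; M <- crcm$M
  R <- crcm$matrix
  n <- K * M
  real_of <- rep(seq_len(K), each = M)
  comp_of <- rep(seq_len(M), K)
  # mask: diagonal blocks and the diagonal itself never seed a group
  Rwork <- R
  for (k in seq_len(K)) {
    idx <- crcm_rows(crcm, k)
    Rwork[idx, idx] <- -Inf
  }
  used <- rep(FALSE, n)
  alignment <- matrix(NA_integer_, nrow = M, ncol = K)
  seeds <- matrix(NA_integer_, nrow = M, ncol = 2L,
                  dimnames = list(NULL, c("realization", "component")))
  for (g in seq_len(M)) {
    Ravail <- Rwork
    Ravail[used, ] <- -Inf
    Ravail[, used] <- -Inf
    top <- which(Ravail == max(Ravail), arr.ind = TRUE)
    # deterministic tie-break: lowest linear (row, col) index
    top <- top[order(top[, 1L], top[, 2L]), , drop = FALSE]
    i <- top[1L, 1L]; j <- top[1L, 2L]
    members <- integer(K)
    members[real_of[i]] <- comp_of[i]
    members[real_of[j]] <- comp_of[j]
    used[c(i, j)] <- TRUE
    seeds[g, ] <- c(real_of[i], comp_of[i])
    for (k in seq_len(K)) {
      if (members[k] != 0L) next
      rows <- crcm_rows(crcm, k)
      score <- (R[rows, i] + R[rows, j]) / 2
      score[used[rows]] <- -Inf
      pick <- which.max(score)   # which.max takes the first maximum: lowest index
      members[k] <- pick
      used[rows[pick]] <- TRUE
    }
    alignment[g, ] <- members
  }
  attr(alignment, "seed") <- seeds
  alignment
}

#' Correlation threshold from the CRCM histogram valley
#'
#' Histograms the upper-triangle, off-diagonal-block absolute correlations
#' into 50 equal bins on `[0, 1]`, smooths with a 3-bin moving average, and
#' returns the bin midpoint of the global minimum strictly between the two
#' highest local maxima. Falls back to 0.5 when fewer than two local maxima
#' are found (no detectable bimodality).
#'
#' @param crcm A [build_crcm()] result.
#' @return A threshold in `[0, 1]`.
#' @export
correlation_threshold <- function(crcm) {
  R <- crcm$matrix; K <- crcm$K; M <- crcm$M
  off <- matrix(TRUE, K * M, K * M)
  for (k in seq_len(K)) {
    idx <- crcm_rows(crcm, k)
    off[idx, idx] <- FALSE
  }
  vals <- R[upper.tri(R) & off]
  breaks <- seq(0, 1, length.out = 51L)
  counts <- graphics::hist(pmin(vals, 1), breaks = breaks, plot = FALSE)$counts
  sm <- stats::filter(counts, rep(1 / 3, 3L), sides = 2L)
  sm[1L] <- mean(counts[1:2]); sm[50L] <- mean(counts[49:50])
  sm <- as.numeric(sm)
  is_max <- vapply(seq_along(sm), function(i) {
    left <- if (i > 1L) sm[i - 1L] else -Inf
    right <- if (i < length(sm)) sm[i + 1L] else -Inf
    sm[i] > left && sm[i] >= right && sm[i] > 0
  }, logical(1))
  peaks <- which(is_max)
  if (length(peaks) < 2L) return(0.5)
  top2 <- peaks[order(sm[peaks], decreasing = TRUE)[1:2]]
  lo <- min(top2); hi <- max(top2)
  if (hi - lo < 2L) return(0.5)
  inner <- (lo + 1L):(hi - 1L)
  # take the middle of a flat minimum plateau (typically a run of empty
  # bins between well-separated modes)
  at_min <- inner[sm[inner] <= min(sm[inner]) + 1e-12]
  valley <- at_min[ceiling(length(at_min) / 2)]
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  mids[valley]
}

#' Reproducibility index of each aligned group
#'
#' For every aligned group, sums the absolute pairwise correlations among
#' its K members that exceed the threshold; values lie in
#' `[0, K*(K-1)/2]`.
#'
#' @param crcm A [build_crcm()] result.
#' @param alignment Result of [align_components()].
#' @param threshold Correlation threshold in `[0, 1]`.
#' @return Numeric vector of length M (one index per aligned group, in
#'   group order).
#' @export
reproducibility_index <- function(crcm, alignment, threshold) {
  threshold <- check_number(threshold, "threshold", min = 0, max = 1)
  K <- crcm$K; M <- crcm$M
  if (!is.matrix(alignment) || nrow(alignment) != M || ncol(alignment) != K) {
    abort_field("alignment", "must be an M x K matrix consistent with the CRCM")
  }
  R <- crcm$matrix
  vapply(seq_len(M), function(g) {
    rows <- (alignment[g, ] - 1L) + (seq_len(K) - 1L) * M + 1L
    sub <- R[rows, rows]
    pair <- sub[upper.tri(sub)]
    sum(pair[pair > threshold])
  }, numeric(1))
}

#' Selectively average aligned components
#'
#' Within each aligned group, members are sign-aligned to the group's seed
#' (flipped when their signed spatial correlation with the seed map is
#' negative) and averaged over the members that have at least one absolute
#' correlation above the threshold within the group. Groups are returned in
#' descending order of reproducibility index. A group with no eligible
#' member is represented by its seed map and flagged.
#'
#' @param stack The `"ica_stack"` the CRCM was built from.
#' @param crcm A [build_crcm()] result.
#' @param alignment Result of [align_components()].
#' @param threshold Correlation threshold.
#' @return A list of class `"raicar_average"`: `maps` (ranked list of
#'   averaged spatial maps), `timecourses` (ranked list of averaged time
#'   courses, or `NULL` when the stack has no mixing matrices), `order`
#'   (group indices in rank order), `index` (reproducibility indices, rank
#'   order), `flagged` (logical, rank order).
#' @export
selective_average <- function(stack, crcm, alignment, threshold) {
  K <- crcm$K; M <- crcm$M
  idx <- reproducibility_index(crcm, alignment, threshold)
  R <- crcm$matrix
  seeds <- attr(alignment, "seed")
  have_mix <- !is.null(stack$mixing)
  avg_one <- function(g) {
    comps <- alignment[g, ]
    rows <- (comps - 1L) + (seq_len(K) - 1L) * M + 1L
    sub <- R[rows, rows]
    diag(sub) <- 0
    eligible <- apply(sub, 1L, max) > threshold
    seed_k <- seeds[g, "realization"]
    seed_map <- stack$spatial_maps[[seed_k]][comps[seed_k], ]
    flagged <- !any(eligible)
    if (flagged) {
      members <- seed_k
    } else {
      members <- which(eligible)
    }
    signs <- vapply(members, function(k) {
      r <- stats::cor(stack$spatial_maps[[k]][comps[k], ], seed_map)
      if (r < 0) -1 else 1
    }, numeric(1))
    map <- Reduce(`+`, Map(function(k, s) s * stack$spatial_maps[[k]][comps[k], ],
                           members, signs)) / length(members)
    tc <- NULL
    if (have_mix) {
      tc <- Reduce(`+`, Map(function(k, s) s * stack$mixing[[k]][, comps[k]],
                            members, signs)) / length(members)
    }
    list(map = map, tc = tc, flagged = flagged)
  }
  rank_order <- order(idx, decreasing = TRUE)
  parts <- lapply(rank_order, avg_one)
  structure(list(
    maps = lapply(parts, `[[`, "map"),
    timecourses = if (have_mix) lapply(parts, `[[`, "tc"),
    order = rank_order,
    index = idx[rank_order],
    flagged = vapply(parts, `[[`, logical(1), "flagged")
  ), class = "raicar_average")
}

#' Select reproducible components and flag subject inclusion
#'
#' Components whose reproducibility index reaches half of the maximum
#' possible value `K*(K-1)/2` are selected; a subject with fewer than
#' `min_components` selected components is flagged for exclusion (too few
#' nodes give fragmented graphs downstream).
#'
#' @param result A [raicar()] result (or any list with fields `index` in
#'   rank order and `order`).
#' @param K Number of realizations.
#' @param min_components Minimum selected components for inclusion
#'   (default 20).
#' @return List with `selected` (logical, rank order), `cutoff`,
#'   `n_selected`, and `included` (logical inclusion flag).
#' @export
select_components <- function(result, K, min_components = 20L) {
  K <- check_count(K, "K", min = 2L)
  cutoff <- K * (K - 1) / 2 * 0.5
  selected <- result$index >= cutoff
  list(
    selected = selected,
    cutoff = cutoff,
    n_selected = sum(selected),
    included = sum(selected) >= min_components
  )
}

#' Run the full reproducibility ranking on one realization stack
#'
#' Convenience wrapper chaining [build_crcm()], [align_components()],
#' [correlation_threshold()], [reproducibility_index()],
#' [selective_average()] and [select_components()].
#'
#' @param stack An `"ica_stack"`.
#' @param min_components Minimum selected components for subject inclusion.
#' @return An object of class `"raicar_result"` with fields `alignment`,
#'   `threshold`, `cutoff`, `index` (rank order), `order`, `maps`,
#'   `timecourses`, `flagged`, `selected`, `n_selected`, `included`, `K`,
#'   `M`.
#' @examples
#' stack <- generate_realization_stack(realization_spec(
#'   n_realizations = 4, n_components = 5, n_reproducible = 3,
#'   n_voxels = 400, seed = 2
#' ))
#' res <- raicar(stack, min_components = 2)
#' res$n_selected
#' @export
raicar <- function(stack, min_components = 20L) {
  crcm <- build_crcm(stack)
  alignment <- align_components(crcm)
  threshold <- correlation_threshold(crcm)
  avg <- selective_average(stack, crcm, alignment, threshold)
  res <- list(
    alignment = alignment, threshold = threshold,
    index = avg$index, order = avg$order,
    maps = avg$maps, timecourses = avg$timecourses,
    flagged = avg$flagged, K = crcm$K, M = crcm$M
  )
  sel <- select_components(res, crcm$K, min_components)
  res$selected <- sel$selected
  res$cutoff <- sel$cutoff
  res$n_selected <- sel$n_selected
  res$included <- sel$included
  structure(res, class = "raicar_result")
}

#' @export
print.raicar_result <- function(x, ...) {
  cat(sprintf(
    "RAICAR result: K = %d realizations, M = %d components\n", x$K, x$M
  ))
  cat(sprintf("  threshold = %.3f, cutoff = %.1f\n", x$threshold, x$cutoff))
  cat(sprintf(
    "  %d reproducible components (subject %s)\n",
    x$n_selected, if (x$included) "included" else "EXCLUDED"
  ))
  invisible(x)
}
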
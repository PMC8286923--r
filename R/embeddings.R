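# Five manifold-learning embeddings operating on a pairwise distance
# matrix: classical MDS, ISOMAP, diffusion maps, Gaussian kernel PCA and a
# distance-only variant of locally linear embedding. All return an
# "fcn_embedding" carrying coordinates plus the eigenspectrum that produced
# them, so the embedding dimension can be chosen by the eigengap.

new_embedding <- function(coordinates, method, params, eigenvalues,
                          ascending = FALSE, discarded = NULL) {
  structure(list(
    coordinates = coordinates, method = method, params = params,
    eigenvalues = eigenvalues, ascending = ascending, discarded = discarded
  ), class = "fcn_embedding")
}

#' @export
print.fcn_embedding <- function(x, ...) {
  cat(sprintf(
    "<fcn_embedding> method = %s, %d points in %d dimensions\n",
    x$method, nrow(x$coordinates), ncol(x$coordinates)
  ))
  invisible(x)
}

# Deterministic eigenvector sign: largest-magnitude entry positive.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

centering_matrix <- function(m) diag(m) - matrix(1 / m, m, m)

#' Classical multidimensional scaling
#'
#' Double-centers the squared distances, `B = -1/2 * H D^2 H`, and takes
#' coordinates `sqrt(lambda_j) * v_j` from the top `p` positive eigenpairs
#' of `B`. With a Euclidean distance matrix this reproduces PCA scores;
#' with a non-Euclidean input (e.g. the cross-correlation pseudo-distance)
#' negative eigenvalues of `B` are discarded and `p` counts positive
#' eigenpairs only.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param p Embedding dimension (at most the number of positive
#'   eigenvalues of `B`).
#' @return An `"fcn_embedding"` with M x p `coordinates` and the full
#'   eigenvalue spectrum of `B`.
#' @export
mds_embed <- function(D, p = 2L) {
  D <- check_distance_matrix(D)
  p <- check_count(p, "p", min = 1L)
  m <- nrow(D)
  H <- centering_matrix(m)
  B <- -0.5 * H %*% (D^2) %*% H
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  npos <- sum(eig$values > tol)
  if (p > npos) {
    rlang::abort(sprintf(
      "p = %d exceeds the %d positive eigenvalues available; choose p <= %d",
      p, npos, npos
    ), class = "fcnembed_validation_error")
  }
  V <- fix_signs(eig$vectors[, seq_len(p), drop = FALSE])
  Y <- sweep(V, 2L, sqrt(eig$values[seq_len(p)]), `*`)
  rownames(Y) <- rownames(D)
  new_embedding(Y, "mds", list(p = p), eig$values)
}

#' k-nearest-neighbor graph from a distance matrix
#'
#' Connects every node to its `k` nearest neighbors by `D` and symmetrizes
#' by union. Reciprocal edge weights `1/d` are recorded alongside the edge
#' lengths; geodesics are computed over the lengths `d`.
#'
#' @param D Distance matrix.
#' @param k Neighbor count, `1 <= k < M`. Ties in distance break by lower
#'   node index.
#' @return A list of class `"nn_graph"`: `graph` (igraph, edge attributes
#'   `length` and `weight = 1/length`), `k`, `connected` flag, and
#'   `component_sizes`.
#' @export
knn_graph <- function(D, k) {
  D <- check_distance_matrix(D)
  m <- nrow(D)
  k <- check_count(k, "k", min = 1L)
  if (k >= m) abort_field("k", "must be smaller than the number of nodes")
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    ord <- order(D[i, -i], seq_len(m - 1L))   # stable: distance then index
    nb <- (seq_len(m)[-i])[ord[seq_len(k)]]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(g, names = FALSE)
  len <- D[cbind(ends[, 1L], ends[, 2L])]
  igraph::E(g)$length <- len
  igraph::E(g)$weight <- 1 / len
  comps <- igraph::components(g)
  structure(list(
    graph = g, k = k, D = D,
    connected = comps$no == 1L,
    component_sizes = as.integer(comps$csize)
  ), class = "nn_graph")
}

#' Geodesic (shortest-path) distances over a neighbor graph
#'
#' All-pairs shortest paths over the edge lengths `d_ij` of the neighbor
#' graph (Dijkstra per source). Errors when the graph is disconnected,
#' reporting the component sizes, since geodesics are then undefined.
#'
#' @param G An `"nn_graph"` from [knn_graph()].
#' @return A symmetric distance matrix tagged `"geodesic"`.
#' @export
geodesic_distances <- function(G) {
  if (!G$connected) {
    rlang::abort(sprintf(
      "neighbor graph is disconnected (component sizes: %s); increase k",
      paste(sort(G$component_sizes, decreasing = TRUE), collapse = ", ")
    ), class = "fcnembed_disconnected_error")
  }
  DG <- igraph::distances(G$graph, weights = igraph::E(G$graph)$length,
                          algorithm = "dijkstra")
  dimnames(DG) <- dimnames(G$D)
  attr(DG, "metric") <- "geodesic"
  DG
}

#' ISOMAP embedding
#'
#' Classical MDS applied to the geodesic distances of the k-nearest
#' neighbor graph: with `k = M - 1` the graph is complete and the result
#' coincides with [mds_embed()].
#'
#' @param D Distance matrix.
#' @param k Neighbor count for the graph (the study grid is 3--6).
#' @param p Embedding dimension.
#' @return An `"fcn_embedding"` (method `"isomap"`).
#' @export
isomap_embed <- function(D, k = 5L, p = 2L) {
  G <- knn_graph(D, k)
  DG <- geodesic_distances(G)
  emb <- mds_embed(DG, p)
  emb$method <- "isomap"
  emb$params <- list(k = k, p = p)
  emb
}

#' Heat-kernel affinity matrix
#'
#' `W_ij = exp(-d(i, j)^2 / sigma)`; the diagonal is exactly 1 and the sum
#' of all weights `S_w` (used for scale selection) is recorded.
#'
#' @param D Distance matrix.
#' @param sigma Positive kernel scale (units of squared distance).
#' @return List of class `"affinity"`: `W`, `sigma`, `S_w`.
#' @export
heat_kernel <- function(D, sigma) {
  D <- check_distance_matrix(D)
  sigma <- check_number(sigma, "sigma", min = 0, strict_min = TRUE)
  W <- exp(-D^2 / sigma)
  structure(list(W = W, sigma = sigma, S_w = sum(W)), class = "affinity")
}

#' Select the heat-kernel scale from the sum-of-weights curve
#'
#' For each candidate `sigma`, computes the median across subjects of the
#' total affinity `S_w(sigma)`; this curve is sigmoidal in `log(sigma)`,
#' rising from M (identity-like kernel) to M^2 (all-ones kernel). The
#' selected `sigma*` maximizes the central-finite-difference slope of the
#' median curve against `log(sigma)`, and the "linear region" is the
#' maximal contiguous grid interval around `sigma*` where the slope stays
#' within 5% of the maximum.
#'
#' @param Ds List of distance matrices (one per subject), or a single
#'   matrix.
#' @param sigma_grid Strictly increasing grid of at least 5 candidate
#'   scales. Default: 50 log-spaced points spanning
#'   `[0.01, 100] * median(D^2)` pooled over subjects.
#' @return List of class `"sigma_selection"`: `sigma` (the selected
#'   scale), `region` (range of the linear region), `grid`, `median_sw`,
#'   `slope`.
#' @export
select_sigma <- function(Ds, sigma_grid = NULL) {
  if (is.matrix(Ds)) Ds <- list(Ds)
  Ds <- lapply(Ds, check_distance_matrix)
  if (is.null(sigma_grid)) {
    med <- stats::median(unlist(lapply(Ds, function(D) D[upper.tri(D)]^2)))
    sigma_grid <- exp(seq(log(0.01 * med), log(100 * med), length.out = 50L))
  }
  if (length(sigma_grid) < 5L || any(diff(sigma_grid) <= 0)) {
    abort_field("sigma_grid", "must be strictly increasing with >= 5 points")
  }
  sw <- vapply(sigma_grid, function(s) {
    stats::median(vapply(Ds, function(D) heat_kernel(D, s)$S_w, numeric(1)))
  }, numeric(1))
  if (any(diff(sw) < -1e-8)) {
    rlang::abort("sum-of-weights medians are not non-decreasing; invalid distances",
                 class = "fcnembed_validation_error")
  }
  ls <- log(sigma_grid)
  n <- length(ls)
  slope <- numeric(n)
  slope[1L] <- (sw[2L] - sw[1L]) / (ls[2L] - ls[1L])
  slope[n] <- (sw[n] - sw[n - 1L]) / (ls[n] - ls[n - 1L])
  mid <- 2:(n - 1L)
  slope[mid] <- (sw[mid + 1L] - sw[mid - 1L]) / (ls[mid + 1L] - ls[mid - 1L])
  star <- which.max(slope)
  keep <- slope >= 0.95 * slope[star]
  lo <- star
  while (lo > 1L && keep[lo - 1L]) lo <- lo - 1L
  hi <- star
  while (hi < n && keep[hi + 1L]) hi <- hi + 1L
  structure(list(
    sigma = sigma_grid[star],
    region = c(sigma_grid[lo], sigma_grid[hi]),
    grid = sigma_grid, median_sw = sw, slope = slope
  ), class = "sigma_selection")
}

diffusion_operator <- function(D, sigma) {
  aff <- heat_kernel(D, sigma)
  W <- aff$W
  deg <- rowSums(W)
  P <- W / deg
  Pbar <- W / sqrt(outer(deg, deg))   # K^{-1/2} W K^{-1/2}
  list(W = W, deg = deg, P = P, Pbar = Pbar)
}

#' Diffusion-maps embedding
#'
#' Builds the heat-kernel affinity, the row-stochastic diffusion operator
#' `P = K^{-1} W` and its symmetric conjugate `Pbar = K^{-1/2} W K^{-1/2}`
#' (the normalized graph Laplacian form). The eigenvectors of `Pbar` are
#' mapped back through `V = K^{-1/2} U`, the trivial pair
#' `(lambda = 1, constant direction)` is discarded, and the coordinates
#' are `lambda_j^t * v_j` over the next `p` eigenpairs.
#'
#' @param D Distance matrix.
#' @param sigma Heat-kernel scale; see [select_sigma()].
#' @param t Diffusion time (nonnegative integer; default 1).
#' @param p Embedding dimension, `p <= M - 1`.
#' @return An `"fcn_embedding"` (method `"dmaps"`) whose `eigenvalues`
#'   exclude the trivial leading 1 (stored in `discarded`); the operator
#'   `P` is attached as `attr(, "P")` for diffusion-distance work.
#' @export
diffusion_embed <- function(D, sigma, t = 1L, p = 2L) {
  t <- check_count(t, "t", min = 0L)
  p <- check_count(p, "p", min = 1L)
  op <- diffusion_operator(D, sigma)
  m <- nrow(op$P)
  if (p > m - 1L) abort_field("p", "must be at most M - 1")
  eig <- eigen(op$Pbar, symmetric = TRUE)
  V <- eig$vectors / sqrt(op$deg)     # K^{-1/2} U, rows scaled
  lam <- eig$values
  # the trivial eigenvalue 1 leads a connected affinity's spectrum
  V <- fix_signs(V[, -1L, drop = FALSE])
  usable <- lam[-1L]
  sel <- seq_len(p)
  Y <- sweep(V[, sel, drop = FALSE], 2L, usable[sel]^t, `*`)
  rownames(Y) <- rownames(D)
  out <- new_embedding(Y, "dmaps", list(sigma = sigma, t = t, p = p),
                       usable, discarded = lam[1L])
  attr(out, "P") <- op$P
  out
}

#' Diffusion distance between points
#'
#' `D_t(i, j) = sum_m (P^t[i, m] - P^t[j, m])^2`: the squared difference of
#' the t-step transition profiles of i and j. It integrates over all
#' t-step paths, which is what makes it robust to noise compared to a
#' geodesic.
#'
#' @param P Row-stochastic diffusion matrix.
#' @param t Nonnegative integer diffusion time.
#' @return Symmetric matrix tagged `"diffusion"` with zero diagonal.
#' @export
diffusion_distance <- function(P, t = 1L) {
  t <- check_count(t, "t", min = 0L)
  if (max(abs(rowSums(P) - 1)) > 1e-8) abort_field("P", "rows must sum to 1")
  Pt <- diag(nrow(P))
  for (i in seq_len(t)) Pt <- Pt %*% P
  Dt <- as.matrix(stats::dist(Pt))^2
  attr(Dt, "metric") <- "diffusion"
  Dt
}

#' Kernel scale for Gaussian kernel PCA
#'
#' Per-subject rule: the median over rows of each row's minimum
#' off-diagonal distance (the typical nearest-neighbor scale).
#'
#' @param D Distance matrix with `M >= 2`.
#' @return A positive scalar `gamma`.
#' @export
select_gamma <- function(D) {
  D <- check_distance_matrix(D)
  if (nrow(D) < 2L) abort_field("D", "needs at least 2 points")
  row_min <- vapply(seq_len(nrow(D)), function(i) min(D[i, -i]), numeric(1))
  stats::median(row_min)
}

#' Gaussian kernel PCA embedding
#'
#' Kernel `K_ij = exp(-d(i, j)^2 / (2 gamma^2))`, double-centered as
#' `K' = H K H`, eigendecomposed, and the coordinates obtained by
#' projecting `K'` onto its top-`p` eigenvectors. With `gamma` much larger
#' than the data diameter the kernel linearizes and the leading
#' coordinates coincide (up to sign) with PCA scores.
#'
#' @param D Distance matrix.
#' @param gamma Positive kernel width; defaults to [select_gamma()].
#' @param p Embedding dimension, `p <= M - 1`.
#' @return An `"fcn_embedding"` (method `"kpca"`).
#' @export
kpca_embed <- function(D, gamma = NULL, p = 2L) {
  D <- check_distance_matrix(D)
  if (is.null(gamma)) gamma <- select_gamma(D)
  gamma <- check_number(gamma, "gamma", min = 0, strict_min = TRUE)
  p <- check_count(p, "p", min = 1L)
  m <- nrow(D)
  if (p > m - 1L) abort_field("p", "must be at most M - 1")
  K <- exp(-D^2 / (2 * gamma^2))
  H <- centering_matrix(m)
  Kc <- H %*% K %*% H
  Kc <- (Kc + t(Kc)) / 2
  eig <- eigen(Kc, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values))) {
    rlang::abort("centered kernel is not positive semidefinite; invalid distance matrix",
                 class = "fcnembed_validation_error")
  }
  V <- fix_signs(eig$vectors[, seq_len(p), drop = FALSE])
  Y <- Kc %*% V
  rownames(Y) <- rownames(D)
  new_embedding(Y, "kpca", list(gamma = gamma, p = p), eig$values)
}

# Local Gram matrix of point i's neighborhood recovered from pairwise
# distances alone (Saul-Roweis distance-only variant): centre on point i,
# G[j, l] = (d_ij^2 + d_il^2 - d_jl^2) / 2.
local_gram <- function(D, i, nb) {
  dij <- D[i, nb]
  (outer(dij^2, dij^2, `+`) - D[nb, nb]^2) / 2
}

#' Locally linear embedding from pairwise distances
#'
#' Distance-only LLE: each point's k nearest neighbors (by `D`) define a
#' local Gram matrix recovered from squared distances by double-centering
#' on the point; the reconstruction weights solve `G w = 1` normalized to
#' sum 1 (a ridge `1e-9 * tr(G)/k` is added when the local Gram is
#' rank-deficient -- small enough to leave exact local reconstructions
#' intact; see the methods vignette). The embedding comes from the
#' eigenvectors of
#' `W' = (I - W)' (I - W)` for the `p` smallest nonzero eigenvalues (the
#' zero eigenvalue with constant eigenvector is discarded), scaled by
#' `sqrt(M)` so the embedding has unit covariance.
#'
#' @param D Distance matrix.
#' @param k Neighbor count (the study grid is 2--10), `k < M`.
#' @param p Embedding dimension, `p <= M - 1`.
#' @return An `"fcn_embedding"` (method `"lle"`) whose `eigenvalues` are
#'   the nonzero spectrum of `W'` in ascending order (`ascending = TRUE`);
#'   the weight matrix is attached as `attr(, "W")`.
#' @export
lle_embed <- function(D, k = 7L, p = 2L) {
  D <- check_distance_matrix(D)
  m <- nrow(D)
  k <- check_count(k, "k", min = 1L)
  if (k >= m) abort_field("k", "must be smaller than the number of points")
  p <- check_count(p, "p", min = 1L)
  if (p > m - 1L) abort_field("p", "must be at most M - 1")
  W <- matrix(0, m, m)
  for (i in seq_len(m)) {
    ord <- order(D[i, -i], seq_len(m - 1L))
    nb <- (seq_len(m)[-i])[ord[seq_len(k)]]
    G <- local_gram(D, i, nb)
    G <- (G + t(G)) / 2
    if (qr(G)$rank < k) {
      G <- G + diag(1e-9 * sum(diag(G)) / k, k)
    }
    w <- tryCatch(solve(G, rep(1, k)),
                  error = function(e) solve(G + diag(1e-3 * max(sum(diag(G)) / k, 1e-12), k), rep(1, k)))
    W[i, nb] <- w / sum(w)
  }
  Wp <- crossprod(diag(m) - W)
  eig <- eigen((Wp + t(Wp)) / 2, symmetric = TRUE)
  lam <- rev(eig$values)                     # ascending
  U <- eig$vectors[, rev(seq_len(m)), drop = FALSE]
  # discard the zero eigenvalue / constant eigenvector
  lam_usable <- lam[-1L]
  U <- fix_signs(U[, -1L, drop = FALSE])
  Y <- sqrt(m) * U[, seq_len(p), drop = FALSE]
  rownames(Y) <- rownames(D)
  out <- new_embedding(Y, "lle", list(k = k, p = p), lam_usable,
                       ascending = TRUE, discarded = lam[1L])
  attr(out, "W") <- W
  out
}

#' Choose the embedding dimension by the eigengap
#'
#' Sorts the usable eigenvalues (descending; ascending for the LLE
#' convention, where small eigenvalues matter), computes consecutive
#' differences, and returns the position of the largest gap, clamped to
#' `[2, max_p]`. Ties take the smallest dimension.
#'
#' @param spectrum An `"fcn_embedding"`, or a numeric vector of usable
#'   eigenvalues (trivial values already removed).
#' @param max_p Upper cap on the dimension (default 5).
#' @param ascending Set `TRUE` for the LLE convention when passing a bare
#'   vector; ignored when `spectrum` is an embedding.
#' @return An integer dimension in `[2, max_p]`.
#' @export
select_dimension <- function(spectrum, max_p = 5L, ascending = FALSE) {
  max_p <- check_count(max_p, "max_p", min = 2L)
  if (inherits(spectrum, "fcn_embedding")) {
    ascending <- spectrum$ascending
    spectrum <- spectrum$eigenvalues
  }
  lam <- sort(spectrum, decreasing = !ascending)
  if (length(lam) < 3L) abort_field("spectrum", "needs at least 3 usable eigenvalues")
  gaps <- abs(diff(lam))
  p <- which.max(gaps)       # first maximal gap wins on ties
  max(2L, min(p, max_p))
}

#' Pairwise distances in the embedded space
#'
#' Euclidean distances among embedding coordinates -- the matrix the
#' proportional thresholding stage consumes.
#'
#' @param E An `"fcn_embedding"`.
#' @return A symmetric distance matrix tagged `"embedded"`.
#' @export
embedded_distance_matrix <- function(E) {
  if (!inherits(E, "fcn_embedding")) abort_field("E", "must be an fcn_embedding")
  D <- as.matrix(stats::dist(E$coordinates))
  attr(D, "metric") <- "embedded"
  D
}
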
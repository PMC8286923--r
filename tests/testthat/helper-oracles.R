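# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph) so they can arbitrate.

# All-pairs shortest paths by Floyd-Warshall over an edge-length matrix
# (Inf where no edge, 0 on the diagonal).
floyd_warshall <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        cand <- D[i, k] + D[k, j]
        if (cand < D[i, j]) D[i, j] <- cand
      }
    }
  }
  D
}

# Connected components by repeated breadth-first search on a binary
# adjacency matrix; returns a membership vector.
bfs_components <- function(adj) {
  n <- nrow(adj)
  membership <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(membership[s])) next
    comp <- comp + 1L
    queue <- s
    membership[s] <- comp
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] != 0 & is.na(membership))
      membership[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  membership
}

# O(M^3) triplet enumeration: counts (open + closed, closed) triplets.
triplet_counts <- function(adj) {
  n <- nrow(adj)
  total <- 0; closed <- 0
  for (centre in seq_len(n)) {
    nb <- which(adj[centre, ] != 0)
    if (length(nb) < 2L) next
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (b <= a) next
        total <- total + 1
        if (adj[nb[a], nb[b]] != 0) closed <- closed + 1
      }
    }
  }
  c(total = total, closed = closed)
}

# Orthogonal Procrustes residual: RMS distance between X and the best
# rotation/reflection (+ translation) of Y onto X.
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$v %*% t(s$u)
  sqrt(mean((Xc - Yc %*% R)^2))
}

# Random symmetric distance matrix with dyadic-rational entries (exactly
# representable in binary, so shortest-path sums are exact).
random_dyadic_distance <- function(m) {
  v <- sample.int(1024L, m * (m - 1L) / 2L, replace = TRUE) / 256
  D <- matrix(0, m, m)
  D[upper.tri(D)] <- v
  D <- D + t(D)
  attr(D, "metric") <- "euclidean"
  D
}

# Random Euclidean distance matrix from a point cloud.
random_point_distance <- function(m, d = 3L) {
  euclidean_distance(matrix(rnorm(m * max(d, 8L)), m))
}

# Random Erdos-Renyi fcn_graph-compatible binary adjacency with no
# isolated structure constraints.
random_adjacency <- function(m, p_edge = 0.4) {
  adj <- matrix(0L, m, m)
  adj[upper.tri(adj)] <- rbinom(m * (m - 1L) / 2L, 1L, p_edge)
  adj + t(adj)
}

fcn_graph_from_adjacency <- function(adj) {
  D <- 2 - adj        # distance 1 where an edge, 2 where none
  diag(D) <- 0
  attr(D, "metric") <- "euclidean"
  pt <- sum(adj) / 2 / choose(nrow(adj), 2)
  if (pt == 0) stop("empty graph")
  proportional_threshold(D, pt)
}
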
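# The five embeddings, their parameter-selection heuristics, and the
# eigengap dimension rule.

test_that("classical MDS reproduces collinear configurations and PCA scores", {
  # 5 collinear points: a 1-D embedding reproduces the distances exactly
  x <- c(0, 1, 3, 6, 10)
  D <- as.matrix(dist(x))
  attr(D, "metric") <- "euclidean"
  emb <- mds_embed(D, p = 1)
  expect_equal(unname(as.matrix(dist(emb$coordinates))), unname(as.matrix(dist(x))),
               tolerance = 1e-10)

  # Euclidean distances of a random cloud: MDS == PCA up to rotation/sign
  set.seed(81)
  X <- matrix(rnorm(30 * 3), 30)
  emb3 <- mds_embed(euclidean_distance(cbind(X, matrix(0, 30, 5))), p = 3)
  scores <- prcomp(X, center = TRUE)$x[, 1:3]
  expect_lt(procrustes_residual(scores, emb3$coordinates), 1e-8)

  # eigenvalues of B match an independent double-centering oracle
  D2 <- euclidean_distance(matrix(rnorm(12 * 8), 12))
  m <- nrow(D2)
  J <- diag(m) - 1 / m
  B <- -0.5 * J %*% (D2^2) %*% J
  oracle <- sort(eigen((B + t(B)) / 2, symmetric = TRUE)$values, decreasing = TRUE)
  emb2 <- mds_embed(D2, p = 2)
  expect_equal(sort(emb2$eigenvalues, decreasing = TRUE), oracle, tolerance = 1e-10)

  # cross-check against the standard cmdscale implementation
  cs <- cmdscale(D2, k = 2)
  expect_lt(procrustes_residual(cs, emb2$coordinates), 1e-8)
})

test_that("MDS refuses p beyond the positive eigenvalue count", {
  x <- c(0, 1, 2, 4, 7)
  D <- as.matrix(dist(x))
  attr(D, "metric") <- "euclidean"
  expect_error(mds_embed(D, p = 3), "positive eigenvalues")
})

test_that("knn graphs honor k, symmetrize by union, and flag connectivity", {
  set.seed(82)
  D <- random_point_distance(3)
  G <- knn_graph(D, k = 2)
  expect_true(G$connected)
  expect_equal(igraph::ecount(G$graph), 3)  # complete on 3 nodes

  # two well-separated pairs with k = 1: mutually nearest neighbors only
  x <- c(0, 1, 10, 11, 30)
  Dc <- as.matrix(dist(x))
  attr(Dc, "metric") <- "euclidean"
  G1 <- knn_graph(Dc, k = 1)
  expect_false(G1$connected)
  expect_error(geodesic_distances(G1), "disconnected")
  expect_error(knn_graph(Dc, k = 5), "k")
})

test_that("geodesics equal the direct distances on a complete graph", {
  set.seed(83)
  D <- random_point_distance(8)
  G <- knn_graph(D, k = 7)
  expect_equal(unname(geodesic_distances(G)), unname(D), ignore_attr = TRUE)
})

test_that("geodesics equal the Floyd-Warshall oracle on random knn graphs", {
  set.seed(84)
  for (i in 1:10) {
    m <- sample(6:12, 1)
    D <- random_dyadic_distance(m)
    k <- sample(2:4, 1)
    G <- knn_graph(D, k)
    if (!G$connected) next
    L <- matrix(Inf, m, m)
    ends <- igraph::as_edgelist(G$graph, names = FALSE)
    for (e in seq_len(nrow(ends))) {
      L[ends[e, 1], ends[e, 2]] <- L[ends[e, 2], ends[e, 1]] <- D[ends[e, 1], ends[e, 2]]
    }
    expect_equal(unname(geodesic_distances(G)), floyd_warshall(L), ignore_attr = TRUE)
  }
})

test_that("a missing triangle edge routes through the two-hop path", {
  D <- matrix(c(0, 1, 1.9, 1, 0, 1, 1.9, 1, 0), 3)
  attr(D, "metric") <- "euclidean"
  G <- knn_graph(D, k = 1)
  # k = 1 union graph keeps edges (1,2) and (2,3) only
  expect_equal(igraph::ecount(G$graph), 2)
  DG <- geodesic_distances(G)
  expect_equal(DG[1, 3], 2)
})

test_that("ISOMAP with a complete neighbor graph reduces to MDS", {
  set.seed(85)
  D <- random_point_distance(15)
  iso <- isomap_embed(D, k = 14, p = 2)
  mds <- mds_embed(D, p = 2)
  expect_equal(iso$coordinates, mds$coordinates, tolerance = 1e-10)
  expect_equal(iso$method, "isomap")
})

test_that("ISOMAP unrolls a curved arc into its arc-length ordering", {
  set.seed(86)
  theta <- sort(runif(40, 0, pi))
  X <- cbind(cos(theta), sin(theta), matrix(0, 40, 8))
  D <- euclidean_distance(X)
  emb <- isomap_embed(D, k = 5, p = 1)
  ord <- order(emb$coordinates[, 1])
  expect_true(identical(ord, seq_len(40)) || identical(ord, rev(seq_len(40))))
})

test_that("heat kernel obeys its limits and S_w bounds", {
  set.seed(87)
  D <- random_point_distance(6)
  expect_equal(diag(heat_kernel(D, 1)$W), rep(1, 6))
  tiny <- heat_kernel(D, 1e-8)
  expect_equal(tiny$W, diag(6), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tiny$S_w, 6, tolerance = 1e-6)
  huge <- heat_kernel(D, 1e8)
  expect_equal(huge$S_w, 36, tolerance = 1e-4)
  expect_error(heat_kernel(D, 0), "sigma")
})

test_that("sigma selection finds the steep region of the sum-of-weights curve", {
  # two clusters at internal distance ~1 and separation 10: the slope
  # maximum lies between the squared scales 1 and 100
  set.seed(88)
  X <- rbind(matrix(rnorm(10 * 3, sd = 0.3), 10), matrix(rnorm(10 * 3, sd = 0.3) + 10, 10))
  D <- euclidean_distance(cbind(X, matrix(0, 20, 5)))
  sel <- select_sigma(list(D))
  expect_gt(sel$sigma, 1)
  expect_lt(sel$sigma, 1000)
  # S_w medians are non-decreasing in sigma and the region is interior
  expect_true(all(diff(sel$median_sw) >= -1e-9))
  expect_gt(sel$region[1], min(sel$grid))
  expect_lt(sel$region[2], max(sel$grid))
  expect_true(sel$sigma >= sel$region[1] && sel$sigma <= sel$region[2])
})

test_that("the diffusion operator is row-stochastic with matching spectra", {
  set.seed(89)
  D <- random_point_distance(10)
  emb <- diffusion_embed(D, sigma = median(D^2), t = 1, p = 3)
  P <- attr(emb, "P")
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  # leading eigenvalue 1 with a constant right eigenvector
  ep <- eigen(P)
  lead <- order(abs(ep$values), decreasing = TRUE)[1]
  expect_equal(abs(as.numeric(ep$values[lead])), 1, tolerance = 1e-10)
  v <- as.numeric(ep$vectors[, lead])
  expect_lt(diff(range(v / v[1])), 1e-8)
  # spectra of P and the conjugate operator coincide
  lam_p <- sort(Re(ep$values), decreasing = TRUE)
  lam_pbar <- sort(c(emb$discarded, emb$eigenvalues), decreasing = TRUE)
  expect_equal(lam_p, lam_pbar, tolerance = 1e-8)
})

test_that("diffusion time rescales coordinates axis-by-axis", {
  set.seed(90)
  D <- random_point_distance(9)
  sig <- median(D^2)
  e0 <- diffusion_embed(D, sig, t = 0, p = 3)
  e1 <- diffusion_embed(D, sig, t = 1, p = 3)
  e2 <- diffusion_embed(D, sig, t = 2, p = 3)
  lam <- e0$eigenvalues[1:3]
  expect_equal(e1$coordinates, sweep(e0$coordinates, 2, lam, `*`), tolerance = 1e-10)
  expect_equal(e2$coordinates, sweep(e0$coordinates, 2, lam^2, `*`), tolerance = 1e-10)
})

test_that("diffusion distance matches a matrix-power oracle", {
  set.seed(91)
  W <- matrix(runif(16, 0.1, 1), 4)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  P <- W / rowSums(W)
  for (t_ in 0:3) {
    Pt <- diag(4)
    for (s in seq_len(t_)) Pt <- Pt %*% P
    oracle <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      oracle[i, j] <- sum((Pt[i, ] - Pt[j, ])^2)
    }
    expect_equal(unname(diffusion_distance(P, t_)), oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  Dt <- diffusion_distance(P, 2)
  expect_equal(diag(Dt), rep(0, 4), ignore_attr = TRUE)
  # duplicated points: identical rows of P are at diffusion distance 0
  P2 <- P
  P2[2, ] <- P2[1, ]
  expect_equal(diffusion_distance(P2, 2)[1, 2], 0, tolerance = 1e-12)
})

test_that("gamma selection takes the median of per-row nearest distances", {
  D <- matrix(c(0, 0.8, 0.8, 0), 2)
  attr(D, "metric") <- "euclidean"
  expect_equal(select_gamma(D), 0.8)
  # row minima {1, 2, 3} -> median 2
  x <- c(0, 1, 3, 6)
  Dx <- as.matrix(dist(x))  # row minima: 1, 1, 2, 3
  attr(Dx, "metric") <- "euclidean"
  expect_equal(select_gamma(Dx), median(c(1, 1, 2, 3)))
  set.seed(92)
  Dr <- random_point_distance(11)
  oracle <- median(vapply(1:11, function(i) min(Dr[i, -i]), numeric(1)))
  expect_equal(select_gamma(Dr), oracle)
})

test_that("kernel PCA centers correctly and linearizes at large gamma", {
  set.seed(93)
  X <- matrix(rnorm(25 * 3), 25)
  D <- euclidean_distance(cbind(X, matrix(0, 25, 5)))
  emb <- kpca_embed(D, p = 2)
  m <- 25
  K <- exp(-D^2 / (2 * select_gamma(D)^2))
  expect_equal(diag(K), rep(1, m), ignore_attr = TRUE)
  H <- diag(m) - 1 / m
  Kc <- H %*% K %*% H
  expect_lt(max(abs(rowSums(Kc))), 1e-10)

  # gamma far above the data diameter: top coordinates match PCA scores
  big <- kpca_embed(D, gamma = 100 * max(D), p = 2)
  pc <- prcomp(X)$x[, 1:2]
  for (j in 1:2) {
    expect_gte(abs(cor(big$coordinates[, j], pc[, j])), 0.999)
  }
})

test_that("LLE weights reconstruct, the spectrum is anchored at zero, and planes unroll", {
  set.seed(94)
  D <- random_point_distance(20)
  emb <- lle_embed(D, k = 5, p = 2)
  W <- attr(emb, "W")
  nz <- rowSums(W != 0) > 0
  expect_equal(rowSums(W)[nz], rep(1, sum(nz)), tolerance = 1e-10, ignore_attr = TRUE)
  # smallest eigenvalue of W' is zero with a constant eigenvector
  Wp <- crossprod(diag(20) - W)
  es <- eigen((Wp + t(Wp)) / 2, symmetric = TRUE)
  expect_lt(abs(es$values[20]), 1e-8)
  v0 <- es$vectors[, 20]
  expect_lt(diff(range(v0 / v0[1])), 1e-6)
  expect_equal(emb$discarded, es$values[20], tolerance = 1e-10)

  # 50 points on a 2-D affine plane inside 8-D: the embedding is an affine
  # image of the plane coordinates (regression residual ~ 0)
  set.seed(95)
  U <- qr.Q(qr(matrix(rnorm(8 * 2), 8)))
  plane <- matrix(runif(50 * 2, -1, 1), 50)
  X <- plane %*% t(U) + matrix(rnorm(8 * 1), 50, 8, byrow = TRUE)
  Dp <- euclidean_distance(X)
  embp <- lle_embed(Dp, k = 6, p = 2)
  fit <- lm(embp$coordinates ~ plane)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("the eigengap rule selects the dimension with floor 2 and cap 5", {
  expect_equal(select_dimension(c(10, 9.5, 1, 0.9, 0.8)), 2)
  # slow decay with the dominant gap at position 7 -> clamped to the cap 5
  lam <- c(100, 99, 98, 97, 96, 95, 94, 1, 0.9, 0.8)
  expect_equal(select_dimension(lam), 5)
  # all equal: no informative gap, clamp to the floor
  expect_equal(select_dimension(rep(1, 6)), 2)
  expect_error(select_dimension(c(1, 2)), "3 usable")
  # LLE convention: ascending spectrum, gap among the small eigenvalues
  expect_equal(select_dimension(c(0.01, 0.02, 0.03, 5, 6), ascending = TRUE), 3)
})

test_that("embedded distance matrices are plain Euclidean distances of coordinates", {
  co <- matrix(c(0, 3, 7), 3, 1)
  emb <- structure(list(coordinates = co, method = "mds", params = list(),
                        eigenvalues = c(1, 0.5), ascending = FALSE),
                   class = "fcn_embedding")
  DY <- embedded_distance_matrix(emb)
  expect_equal(DY[1, 2], 3)
  expect_equal(DY[1, 3], 7)
  expect_equal(DY[2, 3], 4)
  expect_equal(attr(DY, "metric"), "embedded")

  # round trip: MDS of an exactly Euclidean D at full rank returns D
  set.seed(96)
  X <- matrix(rnorm(10 * 3), 10)
  D <- euclidean_distance(cbind(X, matrix(0, 10, 5)))
  emb_full <- mds_embed(D, p = 3)
  expect_equal(unname(embedded_distance_matrix(emb_full)), unname(D),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("embeddings commute with node permutations up to per-axis sign", {
  set.seed(97)
  D <- random_point_distance(14)
  perm <- sample(14)
  Dp <- D[perm, perm]
  attr(Dp, "metric") <- "euclidean"
  check_perm <- function(emb, embp) {
    A <- emb$coordinates[perm, , drop = FALSE]
    B <- embp$coordinates
    for (j in seq_len(ncol(A))) {
      expect_equal(abs(A[, j]), abs(B[, j]), tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
  check_perm(mds_embed(D, 2), mds_embed(Dp, 2))
  check_perm(kpca_embed(D, gamma = 1, p = 2), kpca_embed(Dp, gamma = 1, p = 2))
  sig <- median(D^2)
  check_perm(diffusion_embed(D, sig, p = 2), diffusion_embed(Dp, sig, p = 2))
})

test_that("geodesics and kernel PCA agree with independent implementations", {
  set.seed(98)
  # vegan computes isomap geodesics with the same k-NN retention rule
  for (i in 1:3) {
    D <- random_point_distance(15)
    G <- knn_graph(D, 4)
    if (!G$connected) next
    vd <- as.matrix(vegan::isomapdist(as.dist(D), k = 4))
    expect_equal(unname(geodesic_distances(G)), unname(vd),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # kernlab's kPCA scores match ours up to per-axis sign
  X <- matrix(rnorm(20 * 8), 20)
  D <- euclidean_distance(X)
  gam <- 1.5
  kp <- kernlab::kpca(X, kernel = "rbfdot",
                      kpar = list(sigma = 1 / (2 * gam^2)), features = 2)
  ours <- kpca_embed(D, gamma = gam, p = 2)
  for (j in 1:2) {
    expect_gt(abs(cor(kernlab::rotated(kp)[, j], ours$coordinates[, j])),
              1 - 1e-8)
  }
})
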
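test_that("alpha-decay kernel hits its closed-form anchor points", {
  # four points on a line; knn = 1 gives sigma = nearest-neighbor distance
  x <- mat_omics(matrix(c(0, 1, 3, 10), 4, 1))
  d <- pairwise_distance(x)
  k <- alpha_decay_kernel(d, knn = 1, decay_alpha = 1)
  expect_equal(diag(unclass(k)), setNames(rep(1, 4), rownames(x)))
  # d12 = sigma1 = sigma2 = 1 -> K12 = exp(-1)
  expect_equal(k[1, 2], exp(-1), tolerance = 1e-12)
  # large alpha: indicator of the local scale
  k400 <- alpha_decay_kernel(d, knn = 1, decay_alpha = 400)
  expect_lt(k400[1, 4], 1e-10)           # d > max(sigma_i, sigma_j)
  # asymmetric mix: d34 = 7 with sigma3 = 2 (far beyond scale, term -> 0)
  # and sigma4 = 7 (exactly at scale, term = exp(-1))
  expect_equal(k400[3, 4], 0.5 * exp(-1), tolerance = 1e-6)
})

test_that("diffusion operator is row-stochastic and structure-preserving", {
  W <- sim_matrix(matrix(1, 2, 2))
  P <- diffusion_operator(W)
  expect_equal(unclass(P), matrix(0.5, 2, 2), ignore_attr = TRUE)
  set.seed(3)
  a <- matrix(runif(36), 6); a <- (a + t(a)) / 2
  P2 <- diffusion_operator(sim_matrix(a))
  expect_equal(rowSums(unclass(P2)), rep(1, 6), ignore_attr = TRUE,
               tolerance = 1e-12)
  blk <- matrix(0, 4, 4); blk[1:2, 1:2] <- 1; blk[3:4, 3:4] <- 1
  P3 <- diffusion_operator(sim_matrix(blk))
  expect_true(all(unclass(P3)[1:2, 3:4] == 0))
  zr <- matrix(0, 2, 2)
  expect_error(diffusion_operator(sim_matrix(zr)), "zero")
})

test_that("diffuse_power equals naive repeated multiplication", {
  P <- diff_op(matrix(0.5, 2, 2))
  expect_equal(unclass(diffuse_power(P, 1)), unclass(P), ignore_attr = TRUE)
  for (t in c(2, 5, 9)) {
    expect_equal(unclass(diffuse_power(P, t)), matrix(0.5, 2, 2),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  set.seed(4)
  for (rep in 1:4) {
    n <- sample(3:6, 1)
    a <- matrix(runif(n * n), n)
    Pm <- a / rowSums(a)
    t <- sample(2:20, 1)
    naive <- Reduce(`%*%`, rep(list(Pm), t))
    got <- diffuse_power(diff_op(Pm), t)
    expect_equal(unclass(got), naive, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(unname(rowSums(unclass(got))), rep(1, n), tolerance = 1e-10)
  }
})

test_that("von Neumann entropy profile behaves and the knee is located", {
  # rank-1 operator: single nonzero eigenvalue, H = 0 at every t
  P1 <- diff_op(matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE))
  v1 <- von_neumann_entropy(P1, 1:10)
  expect_true(all(abs(v1$entropies) < 1e-10))
  # identity operator, n = 2: two equal eigenvalues, H = log 2 at every t
  v2 <- von_neumann_entropy(diff_op(diag(2)), 1:10)
  expect_equal(v2$entropies, rep(log(2), 10), tolerance = 1e-12)
  # H nonincreasing in t on random operators
  set.seed(6)
  for (rep in 1:3) {
    a <- matrix(runif(49), 7); a <- (a + t(a)) / 2; diag(a) <- 1
    P <- diffusion_operator(sim_matrix(a))
    v <- von_neumann_entropy(P, 1:30)
    expect_true(all(diff(v$entropies) <= 1e-10))
    expect_true(v$t_knee %in% 1:30)
  }
})

test_that("potential distances match the two-state closed form", {
  P <- diff_op(matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  pd <- potential_distance(P, eps = 1e-12)
  expect_equal(pd[1, 2], sqrt(2) * abs(log(0.9 / 0.1)), tolerance = 1e-6)
  expect_equal(diag(unclass(pd)), c(s01 = 0, s02 = 0))
  # identical rows at distance zero
  Pr <- diff_op(matrix(c(0.4, 0.6, 0.4, 0.6), 2, byrow = TRUE))
  expect_equal(potential_distance(Pr)[1, 2], 0, tolerance = 1e-12)
  # permutation equivariance
  set.seed(8)
  a <- matrix(runif(25), 5); Pm <- a / rowSums(a)
  pd1 <- potential_distance(diff_op(Pm))
  perm <- sample(5)
  pd2 <- potential_distance(diff_op(Pm[perm, perm]))
  expect_equal(unclass(pd2), unclass(pd1)[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(potential_distance(P, eps = 0), "positive")
})

test_that("MDS reproduces plane-embeddable distances and is deterministic", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 3; D[1, 3] <- D[3, 1] <- 4; D[2, 3] <- D[3, 2] <- 5
  dimnames(D) <- list(letters[1:3], letters[1:3])
  dd <- structure(D, class = c("distance_matrix", "matrix", "array"))
  emb <- mds_embed(dd)
  ed <- as.matrix(dist(emb))
  expect_equal(sort(ed[upper.tri(ed)]), c(3, 4, 5), tolerance = 1e-6)
  expect_equal(colMeans(unclass(emb)), c(DIM1 = 0, DIM2 = 0),
               tolerance = 1e-8)
  emb2 <- mds_embed(dd)
  expect_identical(unclass(emb), unclass(emb2))
  # all-zero distances: all points at the origin
  z <- structure(matrix(0, 3, 3, dimnames = dimnames(D)),
                 class = c("distance_matrix", "matrix", "array"))
  expect_message(e0 <- mds_embed(z), "zero")
  expect_true(all(e0 == 0))
})

test_that("phate separates planted blobs and preserves a planted gradient", {
  x <- blob_pair(n_per = 12, p = 5, sep = 12, seed = 9)
  emb <- phate(x, t = "auto", knn = 3, seed = 1)
  g <- rep(1:2, each = 12)
  cen <- aggregate(cbind(PHATE1, PHATE2) ~ g, data = cbind(emb, g = g), mean)
  between <- sqrt(sum((cen[1, 2:3] - cen[2, 2:3])^2))
  spread <- mean(sqrt((emb$PHATE1 - ave(emb$PHATE1, g))^2 +
                      (emb$PHATE2 - ave(emb$PHATE2, g))^2))
  expect_gt(between, 5 * spread)

  # precomputed-similarity mode with block-diagonal W: exact separation
  blk <- matrix(0, 8, 8); blk[1:4, 1:4] <- 1; blk[5:8, 5:8] <- 1
  embb <- phate(sim_matrix(blk), t = 10, seed = 1)
  s1 <- range(embb$PHATE1[1:4]); s2 <- range(embb$PHATE1[5:8])
  expect_true(s1[2] < s2[1] || s2[2] < s1[1])

  # 1-D latent gradient: PHATE1 tracks the latent order
  set.seed(12)
  u <- sort(runif(60))
  grad <- mat_omics(cbind(10 * u, 10 * u, 10 * u, 10 * u) +
                    matrix(rnorm(240, sd = 0.6), 60))
  embg <- phate(grad, t = "auto", knn = 5, seed = 2)
  expect_gt(abs(cor(embg$PHATE1, u, method = "spearman")), 0.8)
})

test_that("embedding is equivariant to sample permutation up to rigid motion", {
  set.seed(10)
  x <- blob_pair(n_per = 8, p = 4, sep = 6, seed = 10)
  emb <- phate(x, t = 5, knn = 3, seed = 3)
  perm <- sample(16)
  xp <- mat_omics(unclass(x)[perm, ], ids = rownames(x)[perm])
  embp <- phate(xp, t = 5, knn = 3, seed = 3)
  A <- as.matrix(emb[match(embp$sample_id, emb$sample_id), c("PHATE1", "PHATE2")])
  B <- as.matrix(embp[, c("PHATE1", "PHATE2")])
  # Procrustes alignment (rotation/reflection only; both are centered)
  sv <- svd(crossprod(B, A))
  B_rot <- B %*% (sv$u %*% t(sv$v))
  expect_equal(B_rot, A, tolerance = 1e-6, ignore_attr = TRUE)
})
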
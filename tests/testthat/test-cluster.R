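test_that("spectral_eigen returns the normalized-operator spectrum", {
  I5 <- sim_matrix(diag(5))
  es <- spectral_eigen(I5, m = 5)
  expect_equal(es$values, rep(1, 5))

  # exact 2-block matrix of ones (blocks 3 and 2): eigenvalue 1 twice
  blk <- matrix(0, 5, 5)
  blk[1:3, 1:3] <- 1; blk[4:5, 4:5] <- 1
  es2 <- spectral_eigen(sim_matrix(blk), m = 5)
  expect_equal(es2$values[1:2], c(1, 1), tolerance = 1e-12)
  expect_lt(es2$values[3], 1 - 1e-8)

  set.seed(2)
  a <- matrix(runif(49), 7); a <- (a + t(a)) / 2; diag(a) <- 1
  es3 <- spectral_eigen(sim_matrix(a), m = 7)
  expect_true(all(es3$values <= 1 + 1e-8 & es3$values >= -1 - 1e-8))
  expect_error(spectral_eigen(sim_matrix(a), m = 8), "exceed")
})

test_that("dip matches its exact values on hand-checkable samples", {
  expect_equal(dip_statistic(c(0, 1)), 0.25)
  expect_equal(dip_statistic(c(3.7, -1.2)), 0.25)
  for (n in c(3, 5, 10)) {
    expect_equal(dip_statistic(seq_len(n)), 1 / (2 * n), tolerance = 1e-12)
  }
  expect_equal(dip_statistic(rep(4, 8)), 1 / 16)
  # invariant under strictly increasing affine transforms (convexity of the
  # fitted CDF depends on spacing, so only affine maps preserve the dip)
  set.seed(1)
  v <- rnorm(30)
  expect_equal(dip_statistic(v), dip_statistic(2 * v + 1), tolerance = 1e-12)
  expect_equal(dip_statistic(v), dip_statistic(-0.5 * v), tolerance = 1e-12)
})

test_that("dip agrees with the LP oracle on small fixtures", {
  set.seed(99)
  cases <- list(c(0, 1), c(0, 1, 2), c(0, 0.01, 1, 1.01), 1:5,
                c(1, 1, 2, 3), c(0, 0, 1, 1), c(1, 1, 2, 2))
  for (i in 1:18) cases[[length(cases) + 1]] <- round(runif(sample(2:12, 1)), 3)
  for (i in 1:8) cases[[length(cases) + 1]] <-
    sample(1:4, sample(3:12, 1), replace = TRUE)
  oracle <- dip_oracle_batch(cases)
  got <- vapply(cases, dip_statistic, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("multimodality-gap selector recovers planted cluster numbers", {
  # two well-separated blobs, through the diffusion path the pipeline uses
  x <- blob_pair(n_per = 15, p = 4, sep = 10, seed = 5)
  w <- tpg_diffuse(adaptive_kernel(pairwise_distance(x), k_nn = 3),
                   knn_sparsify = 3)
  es <- spectral_eigen(w, m = 7)
  expect_identical(as.integer(select_k_multimodality(es, 2, 6)), 2L)

  # three exact blocks of ones: indicator eigenvectors are maximally bimodal
  blk <- matrix(0, 9, 9)
  blk[1:3, 1:3] <- 1; blk[4:6, 4:6] <- 1; blk[7:9, 7:9] <- 1
  es3 <- spectral_eigen(sim_matrix(blk), m = 6)
  expect_identical(as.integer(select_k_multimodality(es3, 2, 5)), 3L)

  # k_min = k_max returns that value
  expect_identical(as.integer(select_k_multimodality(es3, 4, 4)), 4L)
  expect_error(select_k_multimodality(es3, 2, 9), "exceeds")
})

test_that("eigengap selector picks the largest gap with smallest-K ties", {
  es <- structure(list(values = c(1, 1, 0.2, 0.1),
                       vectors = matrix(0, 4, 4), sample_ids = letters[1:4],
                       source = "sym_normalized"), class = "eigen_system")
  expect_identical(select_k_eigengap(es, 2, 3), 2L)
  flat <- structure(list(values = rep(0.5, 5), vectors = matrix(0, 5, 5),
                         sample_ids = letters[1:5],
                         source = "sym_normalized"), class = "eigen_system")
  expect_identical(select_k_eigengap(flat, 2, 4), 2L)
  blk <- matrix(0, 9, 9)
  blk[1:3, 1:3] <- 1; blk[4:6, 4:6] <- 1; blk[7:9, 7:9] <- 1
  es3 <- spectral_eigen(sim_matrix(blk), m = 6)
  expect_identical(select_k_eigengap(es3, 2, 5), 3L)
})

test_that("cluster_eigenvectors recovers exact and noisy partitions", {
  blk <- matrix(0.01, 10, 10)
  blk[1:6, 1:6] <- 1; blk[7:10, 7:10] <- 1
  es <- spectral_eigen(sim_matrix(blk), m = 4)
  cl <- cluster_eigenvectors(es, 2, seed = 1)
  truth <- rep(c(1, 2), c(6, 4))
  expect_equal(adjusted_rand_index(truth, cl$cluster), 1)
  # labels renumbered by descending size: the 6-block is cluster 1
  expect_identical(cl$cluster[1], 1L)

  # determinism: same seed, same labels
  cl2 <- cluster_eigenvectors(es, 2, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)

  # three planted Gaussian blobs with generous separation
  set.seed(8)
  x <- mat_omics(rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 12), 10),
                       matrix(rnorm(40, -12), 10)))
  es3 <- spectral_eigen(adaptive_kernel(pairwise_distance(x), k_nn = 3), m = 5)
  cl3 <- cluster_eigenvectors(es3, 3, seed = 2)
  expect_equal(adjusted_rand_index(rep(1:3, each = 10), cl3$cluster), 1)

  expect_error(cluster_eigenvectors(es, 11), "exceeds")
})

test_that("clustering is equivariant to sample relabeling", {
  set.seed(31)
  x <- blob_pair(n_per = 10, p = 3, sep = 8, seed = 31)
  es <- spectral_eigen(adaptive_kernel(pairwise_distance(x), k_nn = 3), m = 4)
  cl <- cluster_eigenvectors(es, 2, seed = 9)
  perm <- sample(20)
  xp <- mat_omics(unclass(x)[perm, ], ids = rownames(x)[perm])
  esp <- spectral_eigen(adaptive_kernel(pairwise_distance(xp), k_nn = 3), m = 4)
  clp <- cluster_eigenvectors(esp, 2, seed = 9)
  # same partition up to label permutation
  lab_orig <- cl$cluster[match(clp$sample_id, cl$sample_id)]
  expect_equal(adjusted_rand_index(lab_orig, clp$cluster), 1)
})

test_that("restricted ARI isolates the evaluation subset", {
  truth <- rep(c("a", "b", "c"), each = 4)
  pred_merge <- rep(c(1, 1, 2), each = 4)   # merges a and b
  pred_split <- rep(c(1, 2, 3), each = 4)
  expect_equal(restricted_ari(truth, pred_merge, c("a", "b")), 0)
  expect_equal(restricted_ari(truth, pred_split, c("a", "b")), 1)
  expect_error(restricted_ari(truth, pred_split, "zzz"), "no samples")
})
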
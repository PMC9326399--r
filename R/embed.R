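#' Alpha-decay kernel
#'
#' The heavy-tailed adaptive kernel used for raw-feature diffusion
#' embeddings:
#' \deqn{K_{ij} = \tfrac12 e^{-(d_{ij}/\sigma_i)^\alpha} +
#'   \tfrac12 e^{-(d_{ij}/\sigma_j)^\alpha}}
#' with \eqn{\sigma_i} the distance to the `knn`-th neighbor and
#' \eqn{\alpha} = `decay_alpha`. Large alpha makes the kernel approach a
#' hard knn indicator; zero local scales are floored to the smallest
#' positive scale.
#'
#' @param d A `distance_matrix`.
#' @param knn Neighborhood size for the local scale (default 5).
#' @param decay_alpha Decay exponent (default 40).
#' @return A `similarity_matrix` (provenance `"single_view"`).
#' @export
alpha_decay_kernel <- function(d, knn = 5, decay_alpha = 40) {
  vals <- unclass(d)
  ks <- .knn_scales(vals, knn)
  a <- exp(-(vals / ks$sigma)^decay_alpha)          # rows scaled by sigma_i
  k <- (a + t(a)) / 2
  diag(k) <- 1
  similarity_matrix(k, provenance = "single_view")
}

#' Row-stochastic diffusion operator
#'
#' \eqn{P = D^{-1} W}: each row of the affinity is normalized to sum 1,
#' giving one-step transition probabilities along the data manifold.
#'
#' @param w A `similarity_matrix` (nonnegative, no zero rows).
#' @return Object of class `diffusion_operator`: the matrix with attributes
#'   `t_applied = 1` and `row_sums` (the normalizing masses, kept for
#'   spectral symmetrization).
#' @export
diffusion_operator <- function(w) {
  vals <- unclass(w)
  rs <- rowSums(vals)
  if (any(rs == 0)) stop("zero affinity rows; cannot normalize")
  p <- vals / rs
  structure(p, t_applied = 1L, row_sums = rs,
            class = c("diffusion_operator", "matrix", "array"))
}

.check_stochastic <- function(p) {
  if (max(abs(rowSums(unclass(p)) - 1)) > 1e-10)
    stop("diffusion operator rows do not sum to 1")
  invisible(TRUE)
}

#' Power of a diffusion operator
#'
#' Computes \eqn{P^t} by repeated squaring; row-stochasticity is asserted on
#' the result.
#'
#' @param p A `diffusion_operator`.
#' @param t Positive integer power.
#' @return A `diffusion_operator` with `t_applied` multiplied by `t`.
#' @export
diffuse_power <- function(p, t) {
  t <- as.integer(t)
  if (t < 1L) stop("t must be >= 1")
  base <- unclass(p)
  out <- NULL
  sq <- base
  tt <- t
  while (tt > 0L) {
    if (tt %% 2L == 1L) out <- if (is.null(out)) sq else out %*% sq
    tt <- tt %/% 2L
    if (tt > 0L) sq <- sq %*% sq
  }
  # renormalize away accumulated floating-point drift, then assert
  out <- out / rowSums(out)
  res <- structure(out, t_applied = attr(p, "t_applied") * t,
                   row_sums = attr(p, "row_sums"),
                   class = c("diffusion_operator", "matrix", "array"))
  .check_stochastic(res)
  res
}

#' Von Neumann entropy profile and knee of a diffusion operator
#'
#' For each t in `t_range`, computes \eqn{H(t) = -\sum \eta_i \log \eta_i}
#' over the spectrum of the symmetrized conjugate of \eqn{P^t} (eigenvalues
#' powered, floored at 0, renormalized to sum 1). H(t) decays as diffusion
#' concentrates on fewer meaningful dimensions; the returned `t_knee`
#' maximizes the distance to the straight line joining the profile's
#' endpoints (the "kneedle" rule) and is the automatic choice of diffusion
#' time.
#'
#' @param p A `diffusion_operator` (one-step, `t_applied = 1`).
#' @param t_range Increasing vector of candidate times.
#' @return List with `entropies` and `t_knee`.
#' @export
von_neumann_entropy <- function(p, t_range = 1:100) {
  t_range <- as.integer(t_range)
  if (is.unsorted(t_range, strictly = TRUE)) stop("t_range must be increasing")
  vals <- unclass(p)
  rs <- attr(p, "row_sums")
  if (!is.null(rs)) {
    # P = D^-1 W shares its spectrum with the symmetric D^-1/2 W D^-1/2
    M <- vals * sqrt(rs) / rep(sqrt(rs), each = nrow(vals))
    M <- (M + t(M)) / 2
    lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  } else {
    lam <- Re(eigen(vals, only.values = TRUE)$values)
  }
  H <- vapply(t_range, function(t) {
    eta <- pmax(lam, 0)^t
    s <- sum(eta)
    if (s == 0) return(0)
    eta <- eta[eta > 0] / s
    -sum(eta * log(eta))
  }, numeric(1))
  if (length(t_range) < 3L) return(list(entropies = H, t_knee = t_range[1L]))
  x1 <- t_range[1L]; y1 <- H[1L]
  x2 <- t_range[length(t_range)]; y2 <- H[length(H)]
  denom <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  dist_line <- abs((y2 - y1) * t_range - (x2 - x1) * H + x2 * y1 - y2 * x1) /
    max(denom, .Machine$double.eps)
  list(entropies = H, t_knee = t_range[which.max(dist_line)])
}

#' Diffusion potential distances
#'
#' Transforms transition rows into log-potentials
#' \eqn{U_i = -\log(P_{i\cdot} + \epsilon)} (or square-root potentials
#' \eqn{U_i = \sqrt{P_{i\cdot}}}) and returns the Euclidean distances
#' between potential rows. The epsilon floor keeps the log finite for
#' unreachable states and is explicit for reproducibility.
#'
#' @param p A `diffusion_operator` (typically after [diffuse_power()]).
#' @param eps Positive floor inside the log (default 1e-12).
#' @param potential `"log"` (default) or `"sqrt"`.
#' @return A `distance_matrix`.
#' @export
potential_distance <- function(p, eps = 1e-12, potential = c("log", "sqrt")) {
  potential <- match.arg(potential)
  if (potential == "log" && eps <= 0) stop("eps must be positive")
  vals <- unclass(p)
  U <- if (potential == "log") -log(vals + eps) else sqrt(vals)
  d <- as.matrix(stats::dist(U))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(vals)
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' Metric MDS by classical initialization + SMACOF majorization
#'
#' Double-centering (classical) MDS provides the 2-D initialization; stress
#' is then minimized by SMACOF (Guttman transform) iterations, which
#' guarantee nonincreasing stress, until the relative stress change drops
#' below 1e-8 or `max_iter` is hit. Output coordinates are mean-centered and
#' rotated to principal axes.
#'
#' @param d A `distance_matrix` (symmetric, zero diagonal).
#' @param ndim Embedding dimension (default 2).
#' @param max_iter SMACOF iteration cap (default 300).
#' @param seed Unused by the deterministic classical start; kept so callers
#'   can fix it uniformly.
#' @return Matrix n x ndim with attribute `stress` (final raw stress) and
#'   class `mds_embedding`.
#' @export
mds_embed <- function(d, ndim = 2L, max_iter = 300L, seed = NULL) {
  dm <- unclass(d)
  n <- nrow(dm)
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (all(dm == 0)) {
    message("mds_embed: all distances zero; returning origin")
    out <- matrix(0, n, ndim, dimnames = list(rownames(dm), NULL))
    return(structure(out, stress = 0,
                     class = c("mds_embedding", "matrix", "array")))
  }
  X <- suppressWarnings(stats::cmdscale(dm, k = ndim))
  if (ncol(X) < ndim)
    X <- cbind(X, matrix(0, n, ndim - ncol(X)))
  stress_of <- function(X) {
    e <- as.matrix(stats::dist(X))
    sum((dm - e)^2) / 2
  }
  s_old <- stress_of(X)
  for (it in seq_len(max_iter)) {
    e <- as.matrix(stats::dist(X))
    ratio <- ifelse(e > 0, dm / e, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- (B %*% X) / n
    s_new <- stress_of(X_new)
    X <- X_new
    if (s_old - s_new < 1e-8 * max(s_old, .Machine$double.eps)) {
      s_old <- s_new
      break
    }
    s_old <- s_new
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  pr <- svd(X, nu = 0)
  X <- X %*% pr$v
  dimnames(X) <- list(rownames(dm), paste0("DIM", seq_len(ndim)))
  structure(X, stress = s_old, class = c("mds_embedding", "matrix", "array"))
}

#' PHATE-style diffusion-potential embedding
#'
#' Composition of the diffusion pipeline: build an affinity (alpha-decay
#' kernel from Euclidean distances in raw-feature mode, or the supplied
#' similarity directly in precomputed mode), row-normalize, raise to the
#' diffusion power `t` (chosen automatically at the von Neumann entropy knee
#' when `t = "auto"`), take log-potential distances, and embed with
#' [mds_embed()].
#'
#' @param x An [omics_matrix()] (raw-feature mode) or a `similarity_matrix`
#'   (precomputed mode).
#' @param t Diffusion time: positive integer or `"auto"`.
#' @param knn,decay_alpha Alpha-decay kernel parameters (raw-feature mode).
#' @param eps Epsilon floor for the log potential.
#' @param potential `"log"` or `"sqrt"`.
#' @param mds_max_iter SMACOF cap.
#' @param seed Passed to [mds_embed()].
#' @return A `data.frame` of class `phate_embedding` with columns
#'   `sample_id`, `PHATE1`, `PHATE2`; attributes `t_used` and `stress`.
#' @export
phate <- function(x, t = "auto", knn = 5, decay_alpha = 40, eps = 1e-12,
                  potential = c("log", "sqrt"), mds_max_iter = 300L,
                  seed = 1L) {
  potential <- match.arg(potential)
  w <- if (inherits(x, "similarity_matrix")) {
    x
  } else {
    alpha_decay_kernel(pairwise_distance(x), knn = knn,
                       decay_alpha = decay_alpha)
  }
  p1 <- diffusion_operator(w)
  if (identical(t, "auto")) {
    vne <- von_neumann_entropy(p1, t_range = 1:100)
    t <- vne$t_knee
  }
  pt <- diffuse_power(p1, t)
  pd <- potential_distance(pt, eps = eps, potential = potential)
  emb <- mds_embed(pd, ndim = 2L, max_iter = mds_max_iter, seed = seed)
  out <- data.frame(sample_id = rownames(w), PHATE1 = emb[, 1],
                    PHATE2 = emb[, 2], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, t_used = t, stress = attr(emb, "stress"),
            class = c("phate_embedding", "data.frame"))
}
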
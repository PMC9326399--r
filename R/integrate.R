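#' Combine per-modality similarity matrices by kernel addition
#'
#' Elementwise sum with equal weights, the linear combination used upstream
#' of tensor-product-graph diffusion. All views must share sample ids and
#' ordering.
#'
#' @param views List of `similarity_matrix` objects.
#' @return A `similarity_matrix` with provenance `"combined"`.
#' @export
combine_kernels <- function(views) {
  if (!is.list(views) || !length(views)) stop("need a nonempty list of views")
  ids <- rownames(views[[1]])
  for (v in views) {
    if (!identical(rownames(v), ids))
      stop("views do not share sample ids/order; align first")
  }
  out <- Reduce(`+`, lapply(views, unclass))
  similarity_matrix(out, provenance = "combined")
}

# keep each row's `k` strongest off-diagonal entries, symmetrized by union
.knn_sparsify <- function(a, k) {
  n <- nrow(a)
  if (k >= n) stop("knn_sparsify must be smaller than n")
  keep <- matrix(FALSE, n, n)
  off <- a
  diag(off) <- -Inf
  for (i in seq_len(n)) {
    ord <- order(off[i, ], decreasing = TRUE)[seq_len(k)]
    keep[i, ord] <- TRUE
  }
  keep <- keep | t(keep)
  s <- a
  s[!keep] <- 0
  diag(s) <- 0
  s
}

#' Core tensor-product-graph iteration
#'
#' Iterates \eqn{Q_{t+1} = S Q_t S^\top + I} from \eqn{Q_1 = S} until the
#' Frobenius change falls below `tol` or `max_iter` is reached. This is the
#' implicit form of one diffusion step on the tensor-product graph whose
#' nodes are ordered sample pairs: vectorized, the same update reads
#' \eqn{q_{t+1} = (S \otimes S) q_t + vec(I)}, but the `n^2 x n^2` operator is
#' never materialized. Convergence requires spectral radius < 1, which is
#' asserted before iterating.
#'
#' @param S Square substochastic matrix (the normalized, sparsified graph).
#' @param tol Frobenius-norm convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List with `Q` (the converged matrix), `iterations`, and the final
#'   change `delta`.
#' @export
tpg_iterate <- function(S, tol = 1e-10, max_iter = 30) {
  rho <- max(abs(eigen(S, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("spectral radius %.4f >= 1: diffusion would not converge", rho))
  I <- diag(nrow(S))
  Q <- S
  delta <- Inf
  it <- 0L
  while (it < max_iter && delta >= tol) {
    Qn <- S %*% Q %*% t(S) + I
    delta <- sqrt(sum((Qn - Q)^2))
    Q <- Qn
    it <- it + 1L
  }
  list(Q = Q, iterations = it, delta = delta)
}

#' Tensor-product-graph diffusion of a combined similarity
#'
#' Denoises/integrates an affinity matrix by diffusion on its tensor-product
#' graph: (1) keep each row's `knn_sparsify` strongest off-diagonal entries
#' (union-symmetrized); (2) normalize the sparsified matrix by the dense row
#' sums of the input, making rows strictly substochastic; (3) run
#' [tpg_iterate()]; (4) symmetrize. The sparsification confines diffusion to
#' reliable local neighborhoods while the dense-sum normalization keeps the
#' operator a contraction.
#'
#' @param a A `similarity_matrix` (symmetric, nonnegative).
#' @param knn_sparsify Neighbors kept per row (default 10).
#' @param max_iter,tol Iteration controls for [tpg_iterate()].
#' @return A `similarity_matrix` with provenance `"diffused"`; the number of
#'   iterations used is attached as attribute `iterations`.
#' @export
tpg_diffuse <- function(a, knn_sparsify = 10, max_iter = 30, tol = 1e-10) {
  vals <- unclass(a)
  rs <- rowSums(vals)
  if (any(rs == 0)) {
    bad <- rownames(vals)[rs == 0]
    stop("all-zero similarity rows (disconnected samples): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  s <- .knn_sparsify(vals, knn_sparsify)
  S <- s / rs                          # rows strictly substochastic
  res <- tpg_iterate(S, tol = tol, max_iter = max_iter)
  Q <- (res$Q + t(res$Q)) / 2
  dimnames(Q) <- dimnames(vals)
  out <- similarity_matrix(Q, provenance = "diffused")
  attr(out, "iterations") <- res$iterations
  out
}
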
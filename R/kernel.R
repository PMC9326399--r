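#' Euclidean distance matrix between samples
#'
#' @param m An [omics_matrix()] or plain numeric matrix (samples in rows).
#' @return A symmetric `n x n` matrix of class `distance_matrix` with zero
#'   diagonal; exact symmetry is enforced by averaging with the transpose.
#' @export
pairwise_distance <- function(m) {
  vals <- unclass(m)
  if (!all(is.finite(vals))) stop("non-finite values in input matrix")
  if (nrow(vals) < 2) stop("need at least two samples")
  if (ncol(vals) == 0) stop("input matrix has no features")
  d <- as.matrix(stats::dist(vals, method = "euclidean"))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' Construct a similarity matrix object
#'
#' @param values Symmetric nonnegative `n x n` matrix with sample ids as
#'   dimnames.
#' @param provenance One of `"single_view"`, `"combined"`, `"diffused"`.
#' @return Object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values,
                              provenance = c("single_view", "combined",
                                             "diffused")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (max(abs(values - t(values))) > 1e-10)
    stop("similarity matrix must be symmetric within 1e-10")
  if (min(values) < 0) stop("similarity values must be nonnegative")
  structure(values, provenance = provenance,
            class = c("similarity_matrix", "matrix", "array"))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s]: %d x %d\n",
              attr(x, "provenance"), nrow(x), ncol(x)))
  invisible(x)
}

# distance from each sample to its k-th nearest neighbor (self excluded),
# and the k-NN index sets. Ties broken by sample order (column index).
.knn_scales <- function(d, k) {
  n <- nrow(d)
  if (k >= n) stop("k_nn must be smaller than the number of samples")
  sigma <- numeric(n)
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))   # stable: distance, then sample index
    ord <- ord[ord != i][seq_len(k)]
    nn[i, ] <- ord
    sigma[i] <- d[i, ord[k]]
  }
  if (any(sigma == 0)) {
    pos <- sigma[sigma > 0]
    if (!length(pos)) stop("all local scales are zero (all points identical)")
    message(sprintf(
      "adaptive_kernel: %d zero local scales floored to smallest positive",
      sum(sigma == 0)))
    sigma[sigma == 0] <- min(pos)
  }
  list(sigma = sigma, nn = nn)
}

#' Self-tuning density-aware affinity kernel
#'
#' Converts a distance matrix into a sample-to-sample similarity
#' \deqn{W_{ij} = \exp\left(-\frac{d_{ij}^2}{\sigma_i \sigma_j (CNN_{ij}+1)}\right)}
#' where \eqn{\sigma_i} is the distance from sample i to its `k_nn`-th nearest
#' neighbor (local scale, self excluded) and \eqn{CNN_{ij}} counts common
#' members of the two k-nearest-neighbor sets. The CNN factor amplifies
#' similarity inside locally dense regions; `use_density = FALSE` drops it,
#' reducing to the classical self-tuning (local scaling) kernel.
#'
#' Duplicate points give \eqn{\sigma_i = 0}; those scales are floored to the
#' smallest positive scale observed, with a message.
#'
#' @param d A `distance_matrix` from [pairwise_distance()].
#' @param k_nn Local-scale neighbor index (default 10).
#' @param use_density Include the common-nearest-neighbor density factor?
#' @return A `similarity_matrix` with provenance `"single_view"`, unit
#'   diagonal.
#' @export
adaptive_kernel <- function(d, k_nn = 10, use_density = TRUE) {
  d <- unclass(d)
  n <- nrow(d)
  ks <- .knn_scales(d, k_nn)
  denom <- outer(ks$sigma, ks$sigma)
  if (use_density) {
    memb <- matrix(FALSE, n, n)
    memb[cbind(rep(seq_len(n), each = k_nn), as.integer(t(ks$nn)))] <- TRUE
    cnn <- tcrossprod(memb * 1)         # |NN_k(i) intersect NN_k(j)|
    denom <- denom * (cnn + 1)
  }
  w <- exp(-d^2 / denom)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  similarity_matrix(w, provenance = "single_view")
}

#' Tune the kernel neighborhood size by the multimodality gap
#'
#' For every candidate `k` in `k_grid`, builds the kernel, eigendecomposes the
#' normalized graph and scores the candidate by the maximal dip-statistic drop
#' across consecutive eigenvectors (the same score that drives
#' [select_k_multimodality()]). Returns the `k` with the largest drop; ties go
#' to the smallest `k`.
#'
#' @param d A `distance_matrix`.
#' @param k_grid Candidate neighborhood sizes (default `c(3,5,7,10,15,20)`).
#' @param k_min,k_max Range of cluster numbers scanned by the dip-drop score.
#' @param use_density Passed to [adaptive_kernel()].
#' @return List with `k_star`, the winning `similarity_matrix` (`kernel`),
#'   and the per-candidate scores (`scores`).
#' @export
tune_kernel <- function(d, k_grid = c(3, 5, 7, 10, 15, 20), k_min = 2,
                        k_max = 10, use_density = TRUE) {
  if (!length(k_grid)) stop("k_grid must be nonempty")
  k_grid <- sort(unique(as.integer(k_grid)))
  n <- nrow(d)
  k_grid <- k_grid[k_grid < n]
  if (!length(k_grid)) stop("all k_grid values >= number of samples")
  k_max <- min(k_max, n - 1)
  scores <- numeric(length(k_grid))
  kernels <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    w <- adaptive_kernel(d, k_nn = k_grid[i], use_density = use_density)
    es <- spectral_eigen(w, m = min(n, k_max + 1))
    dips <- apply(es$vectors, 2, dip_statistic)
    hi <- min(k_max, length(dips) - 1)
    drops <- dips[k_min:hi] - dips[(k_min + 1):(hi + 1)]
    scores[i] <- max(drops)
    kernels[[i]] <- w
  }
  best <- which.max(scores)            # which.max takes the first (smallest k)
  list(k_star = k_grid[best], kernel = kernels[[best]],
       scores = stats::setNames(scores, k_grid))
}

#' Write / read a similarity matrix as headered square TSV
#'
#' @param w A `similarity_matrix`.
#' @param path File path.
#' @return The path (write) or a `similarity_matrix` (read).
#' @export
write_similarity <- function(w, path) {
  df <- data.frame(sample_id = rownames(w), signif(unclass(w), 15),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @param provenance Provenance tag to attach on read.
#' @export
read_similarity <- function(path, provenance = "combined") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m <- (m + t(m)) / 2   # undo formatting asymmetry
  similarity_matrix(m, provenance = provenance)
}
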
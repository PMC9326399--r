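#' Eigendecomposition of the symmetric normalized similarity graph
#'
#' Computes the top-`m` eigenpairs of \eqn{D^{-1/2} W D^{-1/2}} (D = diagonal
#' of row sums). Eigenvalues are sorted descending and lie in [-1, 1].
#'
#' Within clusters of (near-)coincident eigenvalues the eigenbasis is not
#' unique — after strong diffusion the leading eigenvalues typically collapse
#' onto 1 and LAPACK returns an arbitrary rotation of the cluster-indicator
#' vectors, which destabilizes any statistic computed per eigenvector. Such
#' blocks (consecutive eigenvalues closer than `degenerate_tol`) are
#' therefore canonicalized: the block's rows are clustered (k-means++ with a
#' fixed internal seed), the cluster indicator vectors are projected onto
#' the block's span, and the projections are orthonormalized by QR — an
#' orthogonal change of basis that restores near-indicator vectors. Columns
#' are then ordered by the position of their largest loading and each sign
#' is fixed so the largest-magnitude entry is positive, making results
#' reproducible across LAPACK builds.
#'
#' @param w A `similarity_matrix`.
#' @param m Number of leading eigenpairs to return (`<= n`).
#' @param degenerate_tol Consecutive eigenvalues closer than this are
#'   treated as one degenerate block for canonicalization (default 1e-3).
#' @return List of class `eigen_system`: `values`, `vectors` (n x m, columns
#'   matched to values), `sample_ids`, `source = "sym_normalized"`.
#' @export
spectral_eigen <- function(w, m = min(nrow(w), 20L), degenerate_tol = 1e-3) {
  vals <- unclass(w)
  n <- nrow(vals)
  if (m > n) stop("m must not exceed the number of samples")
  rs <- rowSums(vals)
  if (any(rs == 0)) stop("zero row sums in similarity matrix")
  inv_sqrt <- 1 / sqrt(rs)
  M <- vals * tcrossprod(inv_sqrt)
  M <- (M + t(M)) / 2
  es <- eigen(M, symmetric = TRUE)
  idx <- seq_len(m)
  vec <- es$vectors[, idx, drop = FALSE]
  lam <- es$values[idx]
  # canonicalize degenerate blocks
  blk_start <- 1L
  for (j in seq_len(m)) {
    ends <- j == m || (lam[blk_start] - lam[j + 1L]) > degenerate_tol
    if (ends) {
      if (j > blk_start) {
        B <- vec[, blk_start:j, drop = FALSE]
        B <- .canonicalize_block(B)
        ord <- order(apply(abs(B), 2, which.max))
        vec[, blk_start:j] <- B[, ord]
      }
      blk_start <- j + 1L
    }
  }
  for (j in seq_len(ncol(vec))) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- rownames(vals)
  structure(list(values = lam, vectors = vec,
                 sample_ids = rownames(vals), source = "sym_normalized"),
            class = "eigen_system")
}

# Lower convex hull of points (x, y) with x strictly increasing, evaluated at
# every x. Monotone-chain construction; collinear middle points are dropped.
.lower_hull_values <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(y)
  hull <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      o <- hull[top - 1L]; a <- hull[top]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross <= 0) top <- top - 1L else break
    }
    top <- top + 1L
    hull[top] <- i
  }
  hull <- hull[seq_len(top)]
  if (length(hull) == 1L) return(rep(y[hull], n))
  stats::approx(x[hull], y[hull], xout = x, method = "linear")$y
}

# Node lists for one mode candidate. Candidates are indexed 1..(2m-1) over
# the m distinct data values: odd index 2j-1 = mode AT value j (the fitted
# unimodal cdf may carry an atom there, so the convex branch ends at the
# left limit F(x_j-) and the concave branch starts at F(x_j)); even index
# 2j = mode strictly between values j and j+1. Bands are [lo0 - eps,
# hi0 + eps] with hi0 = F(x^-) and lo0 = F(x) at each node.
.dip_nodes <- function(cand, x, f_left, f_right) {
  m <- length(x)
  at <- cand %% 2L == 1L
  j <- if (at) (cand + 1L) %/% 2L else cand %/% 2L
  if (at) {
    lseq <- seq_len(j - 1L)
    rrest <- if (j < m) (j + 1L):m else integer(0)
    list(lx = x[seq_len(j)],
         lhi = c(f_left[lseq], f_left[j]),
         llo = c(f_right[lseq], f_left[j]),
         rx = x[j:m],
         rhi = c(f_right[j], f_left[rrest]),
         rlo = c(f_right[j], f_right[rrest]))
  } else {
    list(lx = x[seq_len(j)], lhi = f_left[seq_len(j)],
         llo = f_right[seq_len(j)],
         rx = x[(j + 1L):m], rhi = f_left[(j + 1L):m],
         rlo = f_right[(j + 1L):m])
  }
}

# Hull-based per-branch costs: a convex nondecreasing fit inside the band
# exists iff the lower convex hull of the caps clears the floors; half the
# worst clearance is the minimal eps. Concave branch by reflection.
.eps_hulls <- function(nd) {
  h <- .lower_hull_values(nd$lx, nd$lhi)
  el <- max(0, max(nd$llo - h)) / 2
  l <- -.lower_hull_values(nd$rx, -nd$rlo)
  er <- max(0, max(l - nd$rhi)) / 2
  c(left = el, right = er)
}

# Minimal value at the LAST node of a convex nondecreasing function lying in
# [lo, hi] at nodes x: direct floors plus two-point slope extrapolations
# (a floor at q and a cap at p < q force slope, which convexity propagates
# to the end).
.min_convex_end <- function(x, lo, hi) {
  k <- length(x)
  best <- lo[k]
  if (k >= 3L) {
    for (q in 2L:(k - 1L)) {
      p <- seq_len(q - 1L)
      r <- (x[k] - x[q]) / (x[q] - x[p])
      best <- max(best, max(lo[q] + (lo[q] - hi[p]) * r))
    }
  }
  best
}

# Maximal value at the FIRST node of a concave nondecreasing function in the
# band: point-reflect (x -> -x reversed, y -> 1 - y) and reuse the convex
# form.
.max_concave_start <- function(x, lo, hi) {
  1 - .min_convex_end(rev(-x), rev(1 - hi), rev(1 - lo))
}

# Exact candidate cost: hull feasibility for both branches plus the
# monotone join (convex branch end below concave branch start). The join is
# first certified with the cheap hull witnesses; only if that fails is the
# minimal eps located by bisection on the exact end/start bounds.
.eps_exact <- function(nd, cap = Inf) {
  eh <- max(.eps_hulls(nd))
  join_ok <- function(eps) {
    .min_convex_end(nd$lx, nd$llo - eps, nd$lhi + eps) <=
      .max_concave_start(nd$rx, nd$rlo - eps, nd$rhi + eps)
  }
  if (join_ok(eh)) return(eh)
  # the cost is the least feasible eps: if the join still fails at the
  # caller's current best, this candidate cannot improve on it
  if (is.finite(cap)) {
    if (cap <= eh || !join_ok(cap)) return(Inf)
    lo <- eh; hi <- cap
  } else {
    lo <- eh; hi <- 0.5
  }
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (join_ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Hartigan's dip statistic of a numeric sample
#'
#' Distance from the empirical CDF to the nearest unimodal CDF in sup norm.
#' For each candidate mode position (at a data value, where the fitted CDF
#' may carry an atom, or strictly between two adjacent values) the minimal
#' band half-width making a convex-then-concave nondecreasing fit feasible
#' is computed from greatest-convex-minorant / least-concave-majorant hulls
#' of the band edges plus the monotone join between the two branches; the
#' dip is the minimum over candidates. The hull costs are valley-shaped in
#' the mode position, so candidates are scanned outward from the valley
#' (located by binary search) and the scan stops as soon as the best exact
#' cost beats every remaining lower bound.
#'
#' The attainable minimum is `1/(2n)`; a constant vector returns that value.
#' The dip is invariant under strictly increasing affine transformations of
#' the data (general monotone maps change it: convexity of the fitted CDF
#' depends on the spacing of the values, not only their order).
#'
#' @param v Numeric vector, length >= 2.
#' @return The dip, a nonnegative scalar in `[1/(2n), 1/4]`.
#' @export
dip_statistic <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 2L) stop("dip needs at least two observations")
  if (anyNA(v)) stop("missing values in dip input")
  n <- length(v)
  x_all <- sort(v)
  x <- unique(x_all)
  m <- length(x)
  if (m == 1L) return(1 / (2 * n))
  cnt <- tabulate(match(x_all, x), nbins = m)
  k_hi <- cumsum(cnt)
  f_left <- (k_hi - cnt) / n           # F(x_j^-)
  f_right <- k_hi / n                  # F(x_j)
  n_cand <- 2L * m - 1L
  nodes <- function(i) .dip_nodes(i, x, f_left, f_right)
  hull_cost <- function(i) .eps_hulls(nodes(i))
  # binary search for the valley of the hull lower bound: the left-branch
  # cost is nondecreasing and the right-branch cost nonincreasing in i
  lo <- 1L; hi <- n_cand
  e_lo <- hull_cost(lo); e_hi <- hull_cost(hi)
  if (e_lo["left"] >= e_lo["right"]) {
    hi <- lo
  } else if (e_hi["left"] < e_hi["right"]) {
    lo <- hi
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (hull_cost(mid)["left"] >= hull_cost(mid)["right"]) hi <- mid
      else lo <- mid
    }
  }
  # outward scan from the valley in increasing hull-bound order; the hull
  # cost lower-bounds the exact cost, so the scan certifies optimality
  lb_cache <- rep(NA_real_, n_cand)
  lb <- function(i) {
    if (is.na(lb_cache[i])) lb_cache[i] <<- max(hull_cost(i))
    lb_cache[i]
  }
  left_i <- lo; right_i <- hi
  lb_left <- lb(left_i)
  lb_right <- if (right_i != left_i) lb(right_i) else Inf
  best <- Inf
  repeat {
    nxt_lb <- min(lb_left, lb_right)
    if (!is.finite(nxt_lb) || best <= nxt_lb) break
    if (lb_left <= lb_right) {
      best <- min(best, .eps_exact(nodes(left_i), cap = best))
      left_i <- left_i - 1L
      lb_left <- if (left_i >= 1L) lb(left_i) else Inf
    } else {
      best <- min(best, .eps_exact(nodes(right_i), cap = best))
      right_i <- right_i + 1L
      lb_right <- if (right_i <= n_cand) lb(right_i) else Inf
    }
  }
  max(best, 1 / (2 * n))
}

#' Choose the number of clusters by the multimodality (dip) gap
#'
#' Scores eigenvector `j` of the normalized graph by its dip statistic
#' `d_j`; the selected K is the `j` in `[k_min, k_max - 1]` maximizing the
#' drop `d_j - d_{j+1}` (the last eigenvector that still separates modes),
#' ties going to the smallest `j`.
#'
#' @param es An `eigen_system` from [spectral_eigen()].
#' @param k_min,k_max Search range; `k_max` must not exceed the number of
#'   computed eigenvectors.
#' @return Integer K, with the per-eigenvector dips attached as attribute
#'   `dips`.
#' @export
select_k_multimodality <- function(es, k_min = 2L, k_max = ncol(es$vectors)) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_max > ncol(es$vectors))
    stop("k_max exceeds the number of computed eigenvectors")
  if (k_min >= k_max) return(structure(k_min, dips = NULL))
  dips <- apply(es$vectors[, seq_len(k_max), drop = FALSE], 2, dip_statistic)
  js <- k_min:(k_max - 1L)
  drops <- dips[js] - dips[js + 1L]
  K <- js[which.max(drops)]
  structure(as.integer(K), dips = dips)
}

#' Choose the number of clusters by the eigengap
#'
#' Fallback selector: K maximizing \eqn{\lambda_K - \lambda_{K+1}} over
#' `[k_min, k_max]`, ties to the smallest K.
#'
#' @inheritParams select_k_multimodality
#' @return Integer K.
#' @export
select_k_eigengap <- function(es, k_min = 2L, k_max = length(es$values) - 1L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_max + 1L > length(es$values))
    stop("k_max + 1 exceeds the number of computed eigenvalues")
  if (k_min > k_max) stop("k_min must be <= k_max")
  ks <- k_min:k_max
  gaps <- es$values[ks] - es$values[ks + 1L]
  as.integer(ks[which.max(gaps)])
}

#' Spectral clustering of the leading eigenvectors
#'
#' Takes the first K eigenvectors, row-normalizes every sample's K-vector to
#' unit length (all-zero rows are left at zero), and runs k-means with 50
#' restarts under a fixed seed. Cluster labels are renumbered by descending
#' cluster size for stable cross-run comparison.
#'
#' @param es An `eigen_system`.
#' @param K Number of clusters (>= 2, <= n).
#' @param seed Integer seed controlling the k-means restarts.
#' @param nstart Number of k-means restarts (default 50).
#' @param method_k Label recording how K was chosen.
#' @return A `data.frame` of class `cluster_assignment` with columns
#'   `sample_id`, `cluster`; attributes `K` and `method_k`.
#' @export
cluster_eigenvectors <- function(es, K, seed = 1L, nstart = 50L,
                                 method_k = c("multimodality_gap", "eigengap",
                                              "fixed")) {
  method_k <- match.arg(method_k)
  K <- as.integer(K)
  n <- nrow(es$vectors)
  if (K < 2L) stop("K must be at least 2")
  if (K > n) stop("K exceeds the number of samples")
  U <- es$vectors[, seq_len(K), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  nz <- norms > 0
  U[nz, ] <- U[nz, , drop = FALSE] / norms[nz]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  km <- .kmeans_pp(U, K, nstart = nstart)
  sizes <- tabulate(km$cluster, nbins = K)
  relabel <- integer(K)
  relabel[order(-sizes, seq_len(K))] <- seq_len(K)
  labels <- relabel[km$cluster]
  out <- data.frame(sample_id = es$sample_ids, cluster = as.integer(labels),
                    stringsAsFactors = FALSE)
  structure(out, K = K, method_k = method_k,
            class = c("cluster_assignment", "data.frame"))
}

# Rotate a (near-)degenerate eigenvector block to near-indicator form:
# cluster the rows, project the cluster indicators onto the block's span
# and orthonormalize. Falls back to varimax if the projections are rank
# deficient. Deterministic: the k-means++ draws run under a fixed local
# seed and the caller's RNG state is restored.
.canonicalize_block <- function(B) {
  b <- ncol(B)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(1L)
  km <- tryCatch(.kmeans_pp(B, b, nstart = 10L), error = function(e) NULL)
  if (!is.null(km)) {
    P <- outer(km$cluster, seq_len(b), "==") * 1
    C <- B %*% crossprod(B, P)        # projections of indicators onto span(B)
    qr_ <- qr(C)
    if (qr_$rank == b) return(qr.Q(qr_))
  }
  B %*% stats::varimax(B, normalize = FALSE)$rotmat
}

# k-means with kmeans++ seeding per restart: D^2-weighted center draws make
# every restart cover well-separated masses with high probability, which
# plain uniform seeding fails to do when K point masses are (near)
# orthogonal (the typical post-diffusion geometry).
.kmeans_pp <- function(X, K, nstart = 50L, iter.max = 100L) {
  n <- nrow(X)
  best <- NULL
  for (s in seq_len(nstart)) {
    centers <- matrix(0, K, ncol(X))
    idx <- sample.int(n, 1L)
    centers[1L, ] <- X[idx, ]
    d2 <- rowSums((X - rep(centers[1L, ], each = n))^2)
    for (k in 2L:K) {
      tot <- sum(d2)
      idx <- if (tot <= 0) sample.int(n, 1L)
             else sample.int(n, 1L, prob = d2 / tot)
      centers[k, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums((X - rep(centers[k, ], each = n))^2))
    }
    km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                         iter.max = iter.max))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 means identical partitions up to label
#' permutation, 0 is the expectation under independence.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  mclust::adjustedRandIndex(a, b)
}

#' ARI restricted to samples from chosen true groups
#'
#' The modality-ablation readout: agreement between truth and prediction
#' evaluated only on samples whose true label falls in `groups` (e.g. the
#' hypomethylated group and its expression twin). Near 0 when the pipeline
#' merges the groups, near 1 when it isolates them.
#'
#' @param truth True label vector.
#' @param pred Predicted label vector (same length/order).
#' @param groups True labels defining the evaluation subset.
#' @return Numeric scalar.
#' @export
restricted_ari <- function(truth, pred, groups) {
  keep <- truth %in% groups
  if (!any(keep)) stop("no samples in the requested groups")
  adjusted_rand_index(truth[keep], pred[keep])
}
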
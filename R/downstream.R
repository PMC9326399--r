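#' Default marker panels
#'
#' Gene-symbol panels for the basal composite score: mesenchymal and
#' epithelial marker sums are subtracted from the basal marker sum. The
#' default symbols are kept verbatim as published even where they look like
#' typographical variants of standard symbols (e.g. "CRS", "PEMT", "H1F1A",
#' "SLC2A", "LAMC"); supply `aliases` to [composite_score()] to remap them
#' rather than guessing intent here.
#'
#' @return Named list with character vectors `basal`, `mesenchymal`,
#'   `epithelial`.
#' @export
marker_panels <- function() {
  list(
    basal = c("SLC2A", "SLC16A1", "H1F1A", "LAMC", "COL17A1", "ITGB1",
              "AREG", "EGFR", "CDH3", "KRT16", "KRT17", "KRT14"),
    mesenchymal = c("FN1", "VIM", "ZEB1", "CRS", "TWIST2", "SNAI2", "CDH2"),
    epithelial = c("CLDN4", "CLDN7", "TJP3", "PEMT", "CDH1")
  )
}

.panel_sum <- function(z, genes, label) {
  present <- intersect(genes, colnames(z))
  missing <- setdiff(genes, colnames(z))
  if (length(missing))
    message(sprintf("composite_score: %d %s panel genes absent (%s)",
                    length(missing), label, paste(missing, collapse = ", ")))
  if (!length(present)) return(list(sum = rep(0, nrow(z)), n = 0L))
  list(sum = rowSums(z[, present, drop = FALSE]), n = length(present))
}

#' Basal composite score
#'
#' Per-sample sum of z-scored basal-marker expression minus the sums for the
#' mesenchymal and epithelial panels:
#' \deqn{score_s = \sum_{g \in basal} z_{sg} - \left(\sum_{g \in mes} z_{sg}
#'   + \sum_{g \in epi} z_{sg}\right)}
#' Panel genes missing from the matrix are skipped with a message; if no
#' panel gene at all is present this is an error.
#'
#' @param expr Z-scored expression [omics_matrix()] (samples x genes).
#' @param panel Panel list as from [marker_panels()].
#' @param aliases Optional named character vector mapping panel symbols to
#'   column names actually present (e.g. `c(H1F1A = "HIF1A")`).
#' @return Named numeric vector of per-sample scores.
#' @export
composite_score <- function(expr, panel = marker_panels(), aliases = NULL) {
  z <- unclass(expr)
  if (!is.null(aliases)) {
    panel <- lapply(panel, function(g) {
      hit <- g %in% names(aliases)
      g[hit] <- aliases[g[hit]]
      g
    })
  }
  b <- .panel_sum(z, panel$basal, "basal")
  m <- .panel_sum(z, panel$mesenchymal, "mesenchymal")
  e <- .panel_sum(z, panel$epithelial, "epithelial")
  if (b$n + m$n + e$n == 0L) stop("no panel genes present in expression matrix")
  stats::setNames(b$sum - (m$sum + e$sum), rownames(z))
}

#' Mesenchymal-minus-epithelial (EMT) score
#'
#' Companion score built from the same panel mechanics: mesenchymal marker
#' sum minus epithelial marker sum, increasing with epithelial-mesenchymal
#' transition.
#'
#' @inheritParams composite_score
#' @return Named numeric vector of per-sample scores.
#' @export
emt_score <- function(expr, panel = marker_panels(), aliases = NULL) {
  z <- unclass(expr)
  if (!is.null(aliases)) {
    panel <- lapply(panel, function(g) {
      hit <- g %in% names(aliases)
      g[hit] <- aliases[g[hit]]
      g
    })
  }
  m <- .panel_sum(z, panel$mesenchymal, "mesenchymal")
  e <- .panel_sum(z, panel$epithelial, "epithelial")
  if (m$n + e$n == 0L) stop("no panel genes present in expression matrix")
  stats::setNames(m$sum - e$sum, rownames(z))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test: exact enumeration p-value when the combined
#' sample size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections (the standard
#' `wilcox.test` machinery).
#'
#' @param a,b Numeric vectors.
#' @return List with `U` (Mann-Whitney U for `a`) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 20L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Holm step-down multiple-testing adjustment
#'
#' \eqn{\tilde p_{(i)} = \max_{j \le i} \min(1, (m-j+1) p_{(j)})} over the
#' ascending order statistics, returned in the original order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, elementwise >= the input and <= 1.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Pairwise differential tests between clusters
#'
#' For every requested feature, runs [wilcoxon_rank_sum()] on every
#' unordered pair of clusters and Holm-adjusts across the pairs within each
#' feature.
#'
#' @param expr An [omics_matrix()] (samples x features).
#' @param clusters A `cluster_assignment` (or data.frame with `sample_id`,
#'   `cluster`).
#' @param features Feature ids to test (default: all columns).
#' @return Data frame with columns `feature_id`, `group_a`, `group_b`,
#'   `statistic`, `p_raw`, `p_adj_holm`.
#' @export
pairwise_de <- function(expr, clusters, features = colnames(expr)) {
  z <- unclass(expr)
  idx <- match(clusters$sample_id, rownames(z))
  if (anyNA(idx)) stop("cluster assignment contains unknown samples")
  z <- z[idx, , drop = FALSE]
  labs <- clusters$cluster
  ks <- sort(unique(labs))
  if (length(ks) < 2L) stop("need at least two clusters")
  pairs <- utils::combn(ks, 2)
  features <- intersect(features, colnames(z))
  if (!length(features)) stop("no requested features present")
  rows <- vector("list", length(features))
  for (f in seq_along(features)) {
    v <- z[, features[f]]
    stat <- p <- numeric(ncol(pairs))
    for (q in seq_len(ncol(pairs))) {
      wt <- wilcoxon_rank_sum(v[labs == pairs[1, q]], v[labs == pairs[2, q]])
      stat[q] <- wt$U
      p[q] <- wt$p
    }
    rows[[f]] <- data.frame(feature_id = features[f],
                            group_a = pairs[1, ], group_b = pairs[2, ],
                            statistic = stat, p_raw = p,
                            p_adj_holm = holm_adjust(p),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; censored times reduce the risk set without a
#' drop. The median is the smallest time at which the estimate falls to 0.5
#' or below (`NA` if never reached).
#'
#' @param times Nonnegative survival/censoring times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return List of class `survival_curve`: `time`, `n_risk`, `n_event`,
#'   `surv` (S(t) after each listed time) and `median`.
#' @export
km_curve <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (any(times < 0)) stop("times must be nonnegative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- km_median(fit$time, fit$surv)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv, median = med),
            class = "survival_curve")
}

#' @rdname km_curve
#' @param surv Survival probabilities matched to `time`.
#' @param time Distinct times of the fitted curve.
#' @export
km_median <- function(time, surv) {
  hit <- which(surv <= 0.5)
  if (!length(hit)) return(NA_real_)
  time[hit[1]]
}

#' G-sample log-rank test
#'
#' At each distinct event time, observed minus expected events per group
#' under the hypergeometric model; the chi-square statistic uses the
#' variance (two groups) or the generalized inverse of the covariance
#' matrix (more groups), with `df = g - 1`.
#'
#' @param times Survival/censoring times.
#' @param events 0/1 event indicators.
#' @param groups Group labels (>= 2 distinct; at least one event overall).
#' @return List with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (sum(events) < 1L) stop("log-rank requires at least one event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups, rho = 0)
  df <- nlevels(groups) - 1L
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Survival comparison across clusters
#'
#' Per-cluster Kaplan-Meier curves and medians plus the global log-rank
#' test; per-pair log-rank p-values are Benjamini-Hochberg adjusted across
#' the family of pairwise comparisons.
#'
#' @param clinical A `clinical_table`.
#' @param clusters A `cluster_assignment` aligned to the same samples.
#' @return List with `curves` (per-cluster `survival_curve`), `medians`,
#'   `global` (log-rank result) and `pairwise` (data frame with BH q-values).
#' @export
cluster_survival <- function(clinical, clusters) {
  idx <- match(clusters$sample_id, clinical$sample_id)
  if (anyNA(idx)) stop("clusters contain samples absent from clinical table")
  tt <- clinical$os_months[idx]
  ee <- clinical$os_event[idx]
  gg <- clusters$cluster
  ks <- sort(unique(gg))
  curves <- lapply(ks, function(k) km_curve(tt[gg == k], ee[gg == k]))
  names(curves) <- paste0("cluster_", ks)
  medians <- vapply(curves, function(cv) cv$median, numeric(1))
  global <- logrank_test(tt, ee, gg)
  pairs <- utils::combn(ks, 2)
  pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                   chi2 = NA_real_, p = NA_real_)
  for (q in seq_len(ncol(pairs))) {
    sel <- gg %in% pairs[, q]
    if (sum(ee[sel]) == 0) next
    lr <- logrank_test(tt[sel], ee[sel], gg[sel])
    pw$chi2[q] <- lr$chi2
    pw$p[q] <- lr$p
  }
  pw$q_bh <- stats::p.adjust(pw$p, method = "BH")
  list(curves = curves, medians = medians, global = global, pairwise = pw)
}
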
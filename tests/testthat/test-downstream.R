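test_that("composite and EMT scores follow the panel arithmetic", {
  genes <- unlist(marker_panels(), use.names = FALSE)
  z <- mat_omics(matrix(1, 2, length(genes), dimnames = NULL), feats = genes)
  # 12 basal - (7 mesenchymal + 5 epithelial) = 0 at z = 1
  expect_equal(unname(composite_score(z)), c(0, 0))
  expect_equal(unname(composite_score(mat_omics(
    matrix(0, 2, length(genes)), feats = genes))), c(0, 0))
  z2 <- unclass(z)
  z2[, marker_panels()$mesenchymal] <- -1
  z2[, marker_panels()$epithelial] <- -1
  expect_equal(unname(composite_score(mat_omics(z2, feats = genes))),
               c(24, 24))
  # EMT score is mesenchymal minus epithelial
  expect_equal(unname(emt_score(mat_omics(z2, feats = genes))),
               c(-7 + 5, -7 + 5))

  # missing genes are skipped with a message; aliases remap
  part <- mat_omics(matrix(1, 1, 2), feats = c("KRT14", "HIF1A"))
  expect_message(s <- composite_score(part), "absent")
  expect_equal(unname(s), 1)
  expect_message(s2 <- composite_score(part, aliases = c(H1F1A = "HIF1A")),
                 "absent")
  expect_equal(unname(s2), 2)
  none <- mat_omics(matrix(1, 1, 1), feats = "XYZ")
  expect_error(suppressMessages(composite_score(none)), "no panel genes")
})

test_that("wilcoxon rank-sum: exact enumeration and symmetry", {
  wt <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(wt$U, 0)
  expect_equal(wt$p, 1 / 3, tolerance = 1e-12)   # 2 of C(4,2)=6 rank splits
  a <- c(5, 1, 3); b <- c(5, 1, 3)
  expect_equal(wilcoxon_rank_sum(a, b)$p, 1)
  set.seed(2)
  x <- rnorm(8); y <- rnorm(6)
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
  # large-sample branch still a valid p
  p_big <- wilcoxon_rank_sum(rnorm(30), rnorm(30, 2))$p
  expect_true(p_big > 0 && p_big < 0.01)
})

test_that("holm adjustment matches the brute-force stepdown definition", {
  holm_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    running <- 0
    for (i in seq_len(m)) {
      running <- max(running, min(1, (m - i + 1) * p[o[i]]))
      adj[o[i]] <- running
    }
    adj
  }
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.03, 0.01, 0.04)), c(0.06, 0.03, 0.06))
  set.seed(3)
  for (rep in 1:10) {
    p <- runif(sample(3:8, 1))
    expect_equal(holm_adjust(p), holm_brute(p), tolerance = 1e-12)
    expect_true(all(holm_adjust(p) >= p & holm_adjust(p) <= 1))
  }
})

test_that("pairwise_de tests every cluster pair, Holm within feature", {
  set.seed(4)
  n <- 60
  expr <- mat_omics(cbind(gA = c(rnorm(20, 3), rnorm(40)),
                          gB = rnorm(n)))
  colnames(expr) <- c("gA", "gB")
  cl <- structure(data.frame(sample_id = rownames(expr),
                             cluster = rep(1:3, each = 20)),
                  class = c("cluster_assignment", "data.frame"))
  de <- pairwise_de(expr, cl, features = c("gA", "gB"))
  expect_identical(nrow(de), 6L)                       # 2 features x 3 pairs
  expect_true(all(de$p_adj_holm >= de$p_raw))
  # planted 3-SD shift in cluster 1 is significant after Holm
  expect_lt(min(de$p_adj_holm[de$feature_id == "gA"]), 0.01)
  # two clusters: one pair per feature, p_adj = p_raw
  cl2 <- structure(data.frame(sample_id = rownames(expr),
                              cluster = rep(1:2, each = 30)),
                   class = c("cluster_assignment", "data.frame"))
  de2 <- pairwise_de(expr, cl2, features = "gB")
  expect_identical(nrow(de2), 1L)
  expect_equal(de2$p_adj_holm, de2$p_raw)
})

test_that("Kaplan-Meier estimator matches hand product-limit values", {
  k <- km_curve(1:5, rep(1, 5))
  expect_equal(k$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(k$median, 3)
  # (1, 2+, 3): risk sets 3, 2, 1 -> S = 2/3 at 1, unchanged at 2, 0 at 3
  k2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k2$surv, c(2 / 3, 2 / 3, 0))
  # all censored: S stays 1, median undefined
  k3 <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(k3$surv == 1))
  expect_true(is.na(k3$median))
  # no censoring: KM equals the empirical survival function
  set.seed(5)
  tt <- rexp(40)
  k4 <- km_curve(tt, rep(1, 40))
  emp <- vapply(k4$time, function(t) mean(tt > t), numeric(1))
  expect_equal(k4$surv, emp, tolerance = 1e-12)
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
})

test_that("log-rank matches the hand O-E tabulation and behaves", {
  # A: deaths at 1, 2; B: deaths at 3, 4
  # t=1: E_A=1/2, V=1/4; t=2: E_A=1/3, V=2/9 -> chi2 = (7/6)^2/(17/36)
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chi2, 49 / 17, tolerance = 1e-10)
  expect_identical(lr$df, 1L)

  # identical groups: chi2 = 0, p = 1
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # duplicating all subjects keeps direction, increases chi2
  tt <- c(1, 2, 3, 4); ee <- rep(1, 4); gg <- c("A", "A", "B", "B")
  lr2 <- logrank_test(rep(tt, 2), rep(ee, 2), rep(gg, 2))
  expect_gt(lr2$chi2, lr$chi2)

  # three groups: df = 2
  lr3 <- logrank_test(c(1, 2, 3, 4, 5, 6), rep(1, 6), rep(1:3, each = 2))
  expect_identical(lr3$df, 2L)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("A", "B")), "event")
})

test_that("cluster_survival aggregates curves, medians, and q-values", {
  set.seed(6)
  n <- 90
  cl <- structure(data.frame(sample_id = sprintf("s%02d", 1:n),
                             cluster = rep(1:3, each = 30)),
                  class = c("cluster_assignment", "data.frame"))
  hz <- c(0.02, 0.02, 0.09)[cl$cluster]
  tt <- rexp(n, hz)
  clin <- clinical_table(data.frame(sample_id = cl$sample_id,
                                    os_months = tt, os_event = 1))
  sv <- cluster_survival(clin, cl)
  expect_identical(names(sv$curves), paste0("cluster_", 1:3))
  expect_lt(sv$medians[["cluster_3"]], sv$medians[["cluster_1"]])
  expect_lt(sv$global$p, 0.05)
  expect_true(all(sv$pairwise$q_bh >= sv$pairwise$p, na.rm = TRUE))
})
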
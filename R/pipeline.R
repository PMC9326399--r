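#' Pipeline configuration
#'
#' Collects the stage parameters of the end-to-end analysis. Defaults follow
#' the multimodal workflow: per-modality density-aware kernels (k = 10),
#' equal-weight kernel addition, tensor-product-graph diffusion (10-NN
#' sparsification), multimodality-gap K selection scanned up to 10 (the
#' customary default of spectral clustering tools at cohort scale), and a
#' diffusion-potential embedding of the integrated similarity at t = 200.
#'
#' @param modalities Which modalities to use (the ablation switch); any
#'   subset of `c("expression", "methylation", "microbiome")`.
#' @param k_nn Kernel local-scale neighbor index.
#' @param use_density Include the CNN density factor in the kernel.
#' @param tune Tune the kernel neighborhood per modality over `k_grid`.
#' @param k_grid Candidate kernel neighborhoods when tuning.
#' @param knn_sparsify,max_iter,tol Diffusion controls, see [tpg_diffuse()].
#' @param k_method `"multimodality_gap"`, `"eigengap"` or `"fixed"`.
#' @param k_min,k_max K search range; `k_fixed` used when
#'   `k_method = "fixed"`.
#' @param t Diffusion time for the embedding (integer or `"auto"`).
#' @param scale_expression Z-score expression before the kernel (default
#'   TRUE; methylation betas and log2-CPM abundances enter unscaled).
#' @param de_features Features for pairwise differential testing (default:
#'   the marker panel genes present).
#' @param nstart K-means restarts.
#' @param seed Integer seed controlling clustering restarts and the
#'   embedding.
#' @return List of class `run_config`.
#' @export
run_config <- function(modalities = c("expression", "methylation",
                                      "microbiome"),
                       k_nn = 10L, use_density = TRUE, tune = FALSE,
                       k_grid = c(3L, 5L, 7L, 10L, 15L, 20L),
                       knn_sparsify = 10L, max_iter = 30L, tol = 1e-10,
                       k_method = c("multimodality_gap", "eigengap", "fixed"),
                       k_min = 2L, k_max = 10L, k_fixed = NULL, t = 200L,
                       scale_expression = TRUE, de_features = NULL,
                       nstart = 50L, seed = 1L) {
  k_method <- match.arg(k_method)
  structure(list(modalities = modalities, k_nn = as.integer(k_nn),
                 use_density = use_density, tune = tune, k_grid = k_grid,
                 knn_sparsify = as.integer(knn_sparsify),
                 max_iter = as.integer(max_iter), tol = tol,
                 k_method = k_method, k_min = as.integer(k_min),
                 k_max = as.integer(k_max), k_fixed = k_fixed, t = t,
                 scale_expression = scale_expression,
                 de_features = de_features, nstart = as.integer(nstart),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the integration-clustering-embedding analysis on in-memory matrices
#'
#' Stage order: align samples, filter methylation probes, z-score
#' expression, per-modality kernel (with optional tuning), kernel addition,
#' tensor-product-graph diffusion, spectral clustering with the configured
#' K selector, diffusion-potential embedding of the integrated similarity,
#' composite scores, pairwise differential expression, and per-cluster
#' survival.
#'
#' @param matrices Named list with any of `expression`, `methylation`,
#'   `microbiome` ([omics_matrix()] objects).
#' @param clinical Optional `clinical_table` (enables the survival stage).
#' @param annotation Optional probe annotation (enables probe filtering).
#' @param cfg A [run_config()].
#' @return List of class `tpgfuse_result` with elements `similarity`
#'   (diffused), `eigen`, `K`, `clusters`, `embedding`, `scores`, `de`,
#'   `survival`, `log` (character vector of stage records) and `cfg`.
#' @export
analyze_cohort <- function(matrices, clinical = NULL, annotation = NULL,
                           cfg = run_config()) {
  log <- character(0)
  say <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
  }
  use <- intersect(cfg$modalities, names(matrices))
  if (!length(use)) stop("stage align: no usable modalities")
  matrices <- matrices[use]
  al <- align_samples(matrices, clinical)
  matrices <- al$matrices
  names(matrices) <- use
  clinical <- al$clinical
  n <- nrow(matrices[[1]])
  say("align: %d samples across %s", n, paste(use, collapse = "+"))

  if (!is.null(annotation) && "methylation" %in% use) {
    before <- ncol(matrices$methylation)
    matrices$methylation <- filter_probes(matrices$methylation, annotation)
    say("filter_probes: %d -> %d probes", before,
        ncol(matrices$methylation))
  }
  if (cfg$scale_expression && "expression" %in% use) {
    matrices$expression <- zscore_features(matrices$expression)
    say("zscore: expression scaled")
  }

  views <- vector("list", length(use))
  names(views) <- use
  for (mdl in use) {
    d <- pairwise_distance(matrices[[mdl]])
    if (cfg$tune) {
      tk <- tune_kernel(d, k_grid = cfg$k_grid, k_min = cfg$k_min,
                        k_max = cfg$k_max, use_density = cfg$use_density)
      views[[mdl]] <- tk$kernel
      say("kernel[%s]: tuned k = %d", mdl, tk$k_star)
    } else {
      views[[mdl]] <- adaptive_kernel(d, k_nn = cfg$k_nn,
                                      use_density = cfg$use_density)
      say("kernel[%s]: k = %d", mdl, cfg$k_nn)
    }
  }
  combined <- combine_kernels(views)
  diffused <- tpg_diffuse(combined, knn_sparsify = cfg$knn_sparsify,
                          max_iter = cfg$max_iter, tol = cfg$tol)
  say("tpg_diffuse: converged in %d iterations",
      attr(diffused, "iterations"))

  es <- spectral_eigen(diffused, m = min(n, cfg$k_max + 1L))
  K <- switch(cfg$k_method,
              multimodality_gap = select_k_multimodality(es, cfg$k_min,
                                                         cfg$k_max),
              eigengap = select_k_eigengap(es, cfg$k_min, cfg$k_max),
              fixed = {
                if (is.null(cfg$k_fixed)) stop("k_method=fixed needs k_fixed")
                as.integer(cfg$k_fixed)
              })
  clusters <- cluster_eigenvectors(es, K, seed = cfg$seed,
                                   nstart = cfg$nstart,
                                   method_k = cfg$k_method)
  say("cluster: K = %d (%s)", as.integer(K), cfg$k_method)

  embedding <- phate(diffused, t = cfg$t, seed = cfg$seed)
  say("phate: t = %s, stress = %.6g", as.character(attr(embedding, "t_used")),
      attr(embedding, "stress"))

  scores <- de <- surv <- NULL
  if ("expression" %in% use) {
    expr_z <- if (cfg$scale_expression) matrices$expression
              else zscore_features(matrices$expression)
    scores <- data.frame(sample_id = rownames(expr_z),
                         basal_composite = composite_score(expr_z),
                         emt = emt_score(expr_z),
                         stringsAsFactors = FALSE)
    feats <- cfg$de_features
    if (is.null(feats))
      feats <- intersect(unlist(marker_panels(), use.names = FALSE),
                         colnames(expr_z))
    if (length(feats)) {
      de <- pairwise_de(expr_z, clusters, features = feats)
      say("pairwise_de: %d features x %d cluster pairs", length(feats),
          nrow(de) / length(feats))
    }
  }
  if (!is.null(clinical)) {
    surv <- cluster_survival(clinical, clusters)
    say("survival: global log-rank chi2 = %.4g (p = %.4g)",
        surv$global$chi2, surv$global$p)
  }
  structure(list(similarity = diffused, eigen = es, K = as.integer(K),
                 clusters = clusters, embedding = embedding, scores = scores,
                 de = de, survival = surv, log = log, cfg = cfg),
            class = "tpgfuse_result")
}

#' Run the full pipeline from files and write the artifact bundle
#'
#' Reads the modality matrices (features-by-samples TSV), the clinical
#' table and the probe annotation, runs [analyze_cohort()], and writes
#' `similarity.tsv`, `embedding.tsv`, `clusters.tsv`, `scores.tsv`,
#' `de.tsv`, `survival.tsv`, a `run_log.txt` and a resolved-config snapshot
#' `config.json` (stamped with the config MD5 and seed) into `out_dir`. All
#' artifacts except the log are deterministic given the inputs, the
#' configuration and the seed.
#'
#' @param paths Named list/vector of input paths: any of `expression`,
#'   `methylation`, `microbiome`, plus optional `clinical` and
#'   `probe_annotation`.
#' @param out_dir Output directory.
#' @param cfg A [run_config()].
#' @return The [analyze_cohort()] result, invisibly.
#' @export
run_pipeline <- function(paths, out_dir, cfg = run_config()) {
  paths <- as.list(paths)
  matrices <- list()
  for (mdl in c("expression", "methylation", "microbiome")) {
    if (!is.null(paths[[mdl]]))
      matrices[[mdl]] <- read_omics_matrix(paths[[mdl]],
                                           orientation = "features_by_samples",
                                           modality = mdl)
  }
  clinical <- if (!is.null(paths$clinical)) read_clinical(paths$clinical)
  annotation <- if (!is.null(paths$probe_annotation))
    read_probe_annotation(paths$probe_annotation)
  res <- analyze_cohort(matrices, clinical = clinical,
                        annotation = annotation, cfg = cfg)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_similarity(res$similarity, file.path(out_dir, "similarity.tsv"))
  emb <- as.data.frame(res$embedding)
  emb$PHATE1 <- signif(emb$PHATE1, 12)
  emb$PHATE2 <- signif(emb$PHATE2, 12)
  utils::write.table(emb, file.path(out_dir, "embedding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cl <- as.data.frame(res$clusters)
  cl$K <- attr(res$clusters, "K")
  cl$method_k <- attr(res$clusters, "method_k")
  utils::write.table(cl, file.path(out_dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(res$scores)) {
    sc <- res$scores
    sc$basal_composite <- signif(sc$basal_composite, 12)
    sc$emt <- signif(sc$emt, 12)
    utils::write.table(sc, file.path(out_dir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$de))
    utils::write.table(res$de, file.path(out_dir, "de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$survival)) {
    sv <- res$survival
    tab <- do.call(rbind, lapply(names(sv$curves), function(nm) {
      cv <- sv$curves[[nm]]
      data.frame(group = nm, time = signif(cv$time, 12),
                 n_risk = cv$n_risk, n_event = cv$n_event,
                 surv = signif(cv$surv, 12), median = signif(cv$median, 12),
                 global_chi2 = signif(sv$global$chi2, 12),
                 global_p = signif(sv$global$p, 12),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(tab, file.path(out_dir, "survival.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg_out <- res$cfg
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg_out, cfg_json, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  hash <- unname(tools::md5sum(cfg_json))
  writeLines(c(sprintf("config_md5: %s", hash),
               sprintf("seed: %d", cfg_out$seed),
               sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               res$log),
             file.path(out_dir, "run_log.txt"))
  invisible(res)
}
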
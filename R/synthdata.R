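#' Configuration for the synthetic tri-modal cohort generator
#'
#' The generator plants nine subtypes by default, mirroring the structure a
#' multimodal subtyping analysis is expected to resolve: a virus-marked group
#' (signal in microbiome and expression), a globally hypomethylated group
#' that shares its expression and microbiome profile with `grp_a` and is
#' therefore separable only through methylation, an EMT-like group
#' (mesenchymal markers up, epithelial markers down), two generic
#' expression-defined groups, and a four-band arm carrying a continuous
#' latent gradient `u` expressed in all three modalities (basal-marker
#' expression declining in `u`, a probe module gaining methylation with `u`,
#' and one genus tracking `u`).
#'
#' @param n_per_group Samples per subtype (default 40).
#' @param groups Subtype labels to generate; subset of the default nine.
#' @param n_genes,n_probes,n_genera Feature counts per modality (defaults
#'   200, 500, 60). `n_probes` counts retained probes; 25 SNP-flagged and 25
#'   sex-chromosome decoy probes are appended on top and are expected to be
#'   removed by probe filtering.
#' @param module_size Genes per subtype-specific expression module (default 15).
#' @param effect_size Module shift in within-group SD units (default 2.5).
#' @param gradient_genes Genes in the dedicated expression gradient module
#'   (default 50); their means move by `effect_size` per half-unit of `u`,
#'   half of them rising and half falling.
#' @param gradient_probes Methylation probes whose logit mean rises with `u`
#'   (default 60), anti-correlated with the declining expression gradient.
#' @param meth_gradient_span Total logit change of gradient probes across
#'   `u` in [0,1] (default 2).
#' @param meth_module_size Probes per subtype-specific methylation module
#'   (default 40); every group except the viral one carries one (the
#'   hypomethylated group is instead marked by its global shift), so that
#'   subtype identity is visible to the methylation kernel as it is in real
#'   tumor methylomes.
#' @param meth_effect Logit shift of the per-group methylation modules
#'   (default 1.5), alternating sign across groups.
#' @param micro_module_size Genera per subtype-specific microbiome
#'   signature (default 4) for the EMT-like and the two generic groups; the
#'   hypomethylated group shares the `grp_a` signature (its twin rule), the
#'   viral group is marked by the papillomavirus genus instead.
#' @param micro_effect log2 fold-change of the microbiome signatures
#'   (default 3).
#' @param beta_logit_sd Logit-normal noise SD for beta values (default 0.8).
#' @param purity_genes,purity_loading Number of genes (default 40) and
#'   per-gene loading (default 0.25) of a continuous per-sample purity-like
#'   factor shared by all groups. Tumor cohorts carry such global nuisance
#'   axes (tumor purity, immune/stromal admixture); without one, every
#'   planted subtype would be an exactly separated island, which real
#'   cohorts never are.
#' @param purity_probes,purity_meth_loading Probes carrying the same factor
#'   on the methylation logit scale (defaults 100 and 0.2).
#' @param hypomethyl_shift Global logit shift of the hypomethylated group
#'   (default -1).
#' @param gradient_mode `"banded"` (default): each gradient band is a proper
#'   cluster — `u` concentrated near the band center and a discrete module
#'   marks the band. `"continuous"`: `u` is uniform on [0,1] and bands are
#'   plain quartile labels with no discrete modules — the pure 1-D gradient
#'   cohort used for embedding-gradient checks.
#' @param nb_size Negative-binomial size (dispersion) for microbiome counts
#'   (default 5).
#' @param censor_frac Target overall censoring fraction (default 0.3);
#'   censoring times are uniform with the upper bound calibrated to it.
#' @param hazard_baseline Exponential event rate per month for unlisted
#'   groups (default 0.02).
#' @param hazards Named per-group hazard overrides (default: viral 0.01,
#'   emt 0.06 — a 3x ratio against baseline).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 40L,
                       groups = c("viral", "hypomethyl", "emt", "grp_a",
                                  "grp_c", "grad_1", "grad_2", "grad_3",
                                  "grad_4"),
                       n_genes = 200L, n_probes = 500L, n_genera = 60L,
                       module_size = 15L, effect_size = 2.5,
                       gradient_genes = 50L, gradient_probes = 60L,
                       meth_gradient_span = 2, meth_module_size = 40L,
                       meth_effect = 1.5, micro_module_size = 4L,
                       micro_effect = 3, purity_genes = 40L,
                       purity_loading = 0.25, purity_probes = 100L,
                       purity_meth_loading = 0.2, beta_logit_sd = 0.8,
                       hypomethyl_shift = -1, gradient_mode = c("banded",
                                                                "continuous"),
                       nb_size = 5, censor_frac = 0.3,
                       hazard_baseline = 0.02,
                       hazards = c(viral = 0.01, emt = 0.06),
                       seed = 1L) {
  gradient_mode <- match.arg(gradient_mode)
  cfg <- list(n_per_group = as.integer(n_per_group), groups = groups,
              n_genes = as.integer(n_genes), n_probes = as.integer(n_probes),
              n_genera = as.integer(n_genera),
              module_size = as.integer(module_size),
              effect_size = effect_size,
              gradient_genes = as.integer(gradient_genes),
              gradient_probes = as.integer(gradient_probes),
              meth_gradient_span = meth_gradient_span,
              meth_module_size = as.integer(meth_module_size),
              meth_effect = meth_effect,
              micro_module_size = as.integer(micro_module_size),
              micro_effect = micro_effect,
              purity_genes = as.integer(purity_genes),
              purity_loading = purity_loading,
              purity_probes = as.integer(purity_probes),
              purity_meth_loading = purity_meth_loading,
              beta_logit_sd = beta_logit_sd,
              hypomethyl_shift = hypomethyl_shift,
              gradient_mode = gradient_mode, nb_size = nb_size,
              censor_frac = censor_frac, hazard_baseline = hazard_baseline,
              hazards = hazards, seed = as.integer(seed))
  stopifnot(cfg$n_per_group > 0, cfg$n_genes > 0, cfg$n_probes > 0,
            cfg$n_genera > 1, cfg$module_size >= 0,
            is.finite(cfg$effect_size), cfg$beta_logit_sd > 0,
            cfg$nb_size > 0, cfg$censor_frac >= 0, cfg$censor_frac < 1,
            cfg$hazard_baseline > 0)
  class(cfg) <- "sim_config"
  cfg
}

.logistic <- function(x) 1 / (1 + exp(-x))

# gene name layout: marker panels first, then gradient module, then one
# module per group that has a discrete signature, then fillers
.gene_plan <- function(cfg) {
  panels <- marker_panels()
  panel_genes <- unlist(panels, use.names = FALSE)
  grad_genes <- if (cfg$gradient_genes > 0)
    sprintf("GRADG%03d", seq_len(cfg$gradient_genes)) else character(0)
  grad_groups <- grep("^grad_", cfg$groups, value = TRUE)
  mod_owner <- setdiff(cfg$groups, "hypomethyl")   # hypomethyl = grp_a twin
  if (cfg$gradient_mode == "continuous")
    mod_owner <- setdiff(mod_owner, grad_groups)
  mods <- list()
  if (cfg$module_size > 0) {
    for (g in mod_owner)
      mods[[g]] <- sprintf("MOD_%s_%02d", toupper(g), seq_len(cfg$module_size))
  }
  named <- c(panel_genes, grad_genes, unlist(mods, use.names = FALSE))
  if (length(named) > cfg$n_genes)
    stop(sprintf("n_genes = %d too small for %d structured genes",
                 cfg$n_genes, length(named)))
  fillers <- sprintf("GENE%04d", seq_len(cfg$n_genes - length(named)))
  list(panels = panels, grad_genes = grad_genes, modules = mods,
       gene_ids = c(named, fillers))
}

#' Simulate a sample-matched tri-modal cohort
#'
#' Draws expression (Gaussian on the log scale around planted subtype and
#' gradient mean structure), methylation (logit-normal beta values with the
#' hypomethylated group shifted globally down and a probe module rising with
#' the gradient), microbiome (negative-binomial counts per genus, converted
#' to log2 counts-per-million with one genus elevated in the viral group and
#' one tracking the gradient), clinical survival (exponential times with
#' per-subtype hazards and uniform censoring calibrated to the target
#' fraction), plus a probe annotation carrying SNP-flagged and
#' sex-chromosome decoys, and the ground truth. Fully determined by
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_cohort`: `expression`, `methylation`,
#'   `microbiome` ([omics_matrix()] objects), `clinical`
#'   (`clinical_table`), `annotation` (probe annotation data frame),
#'   `truth` (data frame `sample_id`, `subtype`, `gradient_u`, `hazard`)
#'   and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  groups <- cfg$groups
  npg <- cfg$n_per_group
  n <- npg * length(groups)
  subtype <- rep(groups, each = npg)
  sample_ids <- sprintf("S%03d", seq_len(n))
  grad_groups <- grep("^grad_", groups, value = TRUE)
  n_bands <- max(1L, length(grad_groups))

  # latent gradient
  gradient_u <- rep(NA_real_, n)
  for (bi in seq_along(grad_groups)) {
    sel <- subtype == grad_groups[bi]
    gradient_u[sel] <- if (cfg$gradient_mode == "banded") {
      # concentrated around the band center: each band is a compact cluster
      # rather than a chain, which k-NN graphs would fragment
      (bi - 0.5) / n_bands + stats::runif(sum(sel), -0.06, 0.06)
    } else {
      stats::runif(sum(sel))
    }
  }
  if (cfg$gradient_mode == "continuous" && length(grad_groups)) {
    # relabel bands as quartiles of the continuous u
    sel <- !is.na(gradient_u)
    band <- pmin(floor(gradient_u[sel] * n_bands) + 1L, n_bands)
    subtype[sel] <- grad_groups[band]
  }

  purity <- stats::rnorm(n)

  plan <- .gene_plan(cfg)
  es <- cfg$effect_size

  # ---- expression: baseline log-scale mean per gene + planted structure
  gene_ids <- plan$gene_ids
  base_mu <- stats::rnorm(cfg$n_genes, mean = 6, sd = 1.5)
  mu <- matrix(rep(base_mu, each = n), n, cfg$n_genes,
               dimnames = list(sample_ids, gene_ids))
  for (g in names(plan$modules))
    mu[subtype == g, plan$modules[[g]]] <-
      mu[subtype == g, plan$modules[[g]]] + es
  # hypomethyl is the expression twin of grp_a
  if ("hypomethyl" %in% groups && "grp_a" %in% names(plan$modules))
    mu[subtype == "hypomethyl", plan$modules[["grp_a"]]] <-
      mu[subtype == "hypomethyl", plan$modules[["grp_a"]]] + es
  # EMT group: mesenchymal up, epithelial down
  if ("emt" %in% groups) {
    mu[subtype == "emt", plan$panels$mesenchymal] <-
      mu[subtype == "emt", plan$panels$mesenchymal] + es
    mu[subtype == "emt", plan$panels$epithelial] <-
      mu[subtype == "emt", plan$panels$epithelial] - es
  }
  grad_sel <- !is.na(gradient_u)
  if (any(grad_sel)) {
    u <- gradient_u[grad_sel]
    # basal marker module declines linearly in u
    mu[grad_sel, plan$panels$basal] <-
      mu[grad_sel, plan$panels$basal] + es * (1 - u)
    if (length(plan$grad_genes)) {
      sgn <- rep(c(1, -1), length.out = length(plan$grad_genes))
      mu[grad_sel, plan$grad_genes] <- mu[grad_sel, plan$grad_genes] +
        2 * es * outer(u - 0.5, sgn)
    }
  }
  if (cfg$purity_genes > 0) {
    pg <- cfg$n_genes - seq_len(min(cfg$purity_genes, cfg$n_genes)) + 1L
    mu[, pg] <- mu[, pg] + cfg$purity_loading * purity
  }
  expression <- omics_matrix(
    mu + matrix(stats::rnorm(n * cfg$n_genes), n, cfg$n_genes),
    modality = "expression")

  # ---- methylation: logit-normal betas + decoy probes
  n_decoy <- 50L
  probe_ids <- c(sprintf("cg%06d", seq_len(cfg$n_probes)),
                 sprintf("cgSNP%04d", seq_len(n_decoy / 2)),
                 sprintf("cgSEX%04d", seq_len(n_decoy / 2)))
  probe_mu <- stats::rnorm(cfg$n_probes + n_decoy, 0, 0.7)
  lmat <- matrix(rep(probe_mu, each = n), n, cfg$n_probes + n_decoy,
                 dimnames = list(sample_ids, probe_ids))
  if ("hypomethyl" %in% groups)
    lmat[subtype == "hypomethyl", seq_len(cfg$n_probes)] <-
      lmat[subtype == "hypomethyl", seq_len(cfg$n_probes)] + cfg$hypomethyl_shift
  if (any(grad_sel) && cfg$gradient_probes > 0) {
    gp <- seq_len(min(cfg$gradient_probes, cfg$n_probes))
    lmat[grad_sel, gp] <- lmat[grad_sel, gp] +
      cfg$meth_gradient_span * (gradient_u[grad_sel] - 0.5)
  }
  # subtype methylation modules: every group except viral (marked in
  # expression+microbiome) and hypomethyl (marked by its global shift);
  # gradient bands only in banded mode, where each band is a true cluster
  meth_owner <- setdiff(groups, c("viral", "hypomethyl"))
  if (cfg$gradient_mode == "continuous")
    meth_owner <- setdiff(meth_owner, grad_groups)
  if (cfg$meth_module_size > 0 && length(meth_owner)) {
    p0 <- min(cfg$gradient_probes, cfg$n_probes)
    for (gi in seq_along(meth_owner)) {
      pr <- p0 + (gi - 1L) * cfg$meth_module_size + seq_len(cfg$meth_module_size)
      pr <- pr[pr <= cfg$n_probes]
      if (!length(pr)) next
      sgn <- if (gi %% 2L == 0L) -1 else 1
      lmat[subtype == meth_owner[gi], pr] <-
        lmat[subtype == meth_owner[gi], pr] + sgn * cfg$meth_effect
    }
  }
  if (cfg$purity_probes > 0) {
    pp <- cfg$n_probes - seq_len(min(cfg$purity_probes, cfg$n_probes)) + 1L
    lmat[, pp] <- lmat[, pp] + cfg$purity_meth_loading * purity
  }
  lmat <- lmat + matrix(stats::rnorm(length(lmat), 0, cfg$beta_logit_sd),
                        nrow(lmat), ncol(lmat))
  methylation <- omics_matrix(.logistic(lmat), modality = "methylation")
  annotation <- data.frame(
    probe_id = probe_ids,
    chromosome = c(as.character(rep_len(1:22, cfg$n_probes)),
                   rep("7", n_decoy / 2),
                   rep(c("X", "Y"), length.out = n_decoy / 2)),
    snp_flagged = c(rep(FALSE, cfg$n_probes), rep(TRUE, n_decoy / 2),
                    rep(FALSE, n_decoy / 2)),
    stringsAsFactors = FALSE)

  # ---- microbiome: NB counts -> log2 CPM
  genus_ids <- c("Alphapapillomavirus", "Gradientibacter",
                 sprintf("Genus%03d", seq_len(cfg$n_genera - 2L)))
  genus_mu <- 2^stats::rnorm(cfg$n_genera, mean = 9, sd = 1.5)
  mu_mat <- matrix(rep(genus_mu, each = n), n, cfg$n_genera,
                   dimnames = list(sample_ids, genus_ids))
  if ("viral" %in% groups)
    mu_mat[subtype == "viral", "Alphapapillomavirus"] <-
      mu_mat[subtype == "viral", "Alphapapillomavirus"] * 32
  if (any(grad_sel))
    mu_mat[grad_sel, "Gradientibacter"] <-
      mu_mat[grad_sel, "Gradientibacter"] *
      2^(3 * (gradient_u[grad_sel] - 0.5))
  # subtype microbiome signatures; hypomethyl shares the grp_a signature
  # (it must stay inseparable from grp_a outside methylation)
  micro_owner <- intersect(c("emt", "grp_a", "grp_c"), groups)
  if (cfg$micro_module_size > 0 && length(micro_owner)) {
    for (gi in seq_along(micro_owner)) {
      gn <- 2L + (gi - 1L) * cfg$micro_module_size +
        seq_len(cfg$micro_module_size)
      gn <- gn[gn <= cfg$n_genera]
      if (!length(gn)) next
      sel <- subtype == micro_owner[gi]
      if (micro_owner[gi] == "grp_a" && "hypomethyl" %in% groups)
        sel <- sel | subtype == "hypomethyl"
      mu_mat[sel, gn] <- mu_mat[sel, gn] * 2^cfg$micro_effect
    }
  }
  counts <- matrix(stats::rnbinom(length(mu_mat), mu = as.vector(mu_mat),
                                  size = cfg$nb_size),
                   nrow(mu_mat), ncol(mu_mat), dimnames = dimnames(mu_mat))
  totals <- pmax(rowSums(counts), 1)
  microbiome <- omics_matrix(log2(counts / totals * 1e6 + 1),
                             modality = "microbiome")

  # ---- survival: exponential with per-group hazards, calibrated censoring
  hz <- rep(cfg$hazard_baseline, n)
  for (g in names(cfg$hazards))
    hz[subtype == g] <- cfg$hazards[[g]]
  t_event <- stats::rexp(n, rate = hz)
  if (cfg$censor_frac > 0) {
    cens_p <- function(cmax) mean((1 - exp(-hz * cmax)) / (hz * cmax))
    c_max <- stats::uniroot(function(cm) cens_p(cm) - cfg$censor_frac,
                            interval = c(1e-6, 1e6))$root
    t_cens <- stats::runif(n, 0, c_max)
  } else {
    t_cens <- rep(Inf, n)
  }
  os_months <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  clinical <- clinical_table(data.frame(
    sample_id = sample_ids, os_months = os_months, os_event = os_event,
    hpv_status = ifelse(subtype == "viral", "positive", "negative"),
    subtype_hint = subtype, stringsAsFactors = FALSE))

  truth <- data.frame(sample_id = sample_ids, subtype = subtype,
                      gradient_u = gradient_u, purity = purity, hazard = hz,
                      stringsAsFactors = FALSE)
  structure(list(expression = expression, methylation = methylation,
                 microbiome = microbiome, clinical = clinical,
                 annotation = annotation, truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Tiny deterministic three-group cohort
#'
#' Twelve samples, three subtypes (viral, hypomethylated twin, generic),
#' extreme separation, small feature spaces — the fixture used for exact,
#' hand-auditable tests and byte-level determinism checks. The returned
#' `params` element carries pipeline settings scaled to n = 12 (kernel
#' k = 3, sparsification 3, K search up to 5).
#'
#' @return A `sim_cohort` with an extra `params` element.
#' @export
make_toy_fixture <- function() {
  cfg <- sim_config(n_per_group = 4L,
                    groups = c("viral", "hypomethyl", "grp_a"),
                    n_genes = 30L, n_probes = 40L, n_genera = 12L,
                    module_size = 3L, effect_size = 6,
                    gradient_genes = 0L, gradient_probes = 0L,
                    hypomethyl_shift = -4, beta_logit_sd = 0.4,
                    seed = 42L)
  cohort <- simulate_cohort(cfg)
  cohort$params <- list(k_nn = 3L, knn_sparsify = 3L, k_min = 2L, k_max = 5L,
                        t = 20L, phate_knn = 3L)
  cohort
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits `expression.tsv`, `methylation.tsv`, `microbiome.tsv` (all
#' features-by-samples, the on-disk convention), `clinical.tsv`,
#' `probe_annotation.tsv` and `truth.tsv`.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_omics_matrix(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_omics_matrix(cohort$microbiome, file.path(dir, "microbiome.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$annotation, file.path(dir, "probe_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
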
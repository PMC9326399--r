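# tpgfuse

Multi-omic tumor subtyping by tensor-product-graph diffusion, spectral
clustering with dip-statistic model selection, and diffusion-potential
embedding.

Head-and-neck (and other) tumor cohorts profiled on several molecular
layers — bulk expression, DNA-methylation beta values, microbial
log2-CPM abundances — rarely reveal their full subtype structure through
any single layer: an HPV-driven group is marked in the virome and the
transcriptome, while an NSD1-like hypomethylated group may be invisible
outside the methylome. `tpgfuse` implements, as a tested R package plus a
small analysis workflow, the integration strategy that resolves this:
fuse the layers into one sample-to-sample similarity, denoise it by graph
diffusion, and cluster and embed the fused graph. A synthetic tri-modal
cohort generator with planted subtypes, gradients and survival provides
ground truth, so every stage is verifiable at desk scale.

## The method

For each modality, a samples x features matrix (expression z-scored;
betas and log2-CPM as delivered) is turned into a self-tuning,
density-aware affinity

    W_ij = exp( -d_ij^2 / ( sigma_i sigma_j (CNN_ij + 1) ) )

with `d_ij` the Euclidean distance, `sigma_i` the distance to the k-th
nearest neighbour (k = 10) and `CNN_ij` the number of shared
k-nearest-neighbours, which amplifies similarity inside dense regions.
The per-modality affinities are combined by equal-weight kernel addition
and integrated by tensor-product-graph diffusion: the combined matrix is
sparsified to each row's 10 strongest links, normalized by the dense row
sums to a strictly substochastic `S`, and iterated

    Q_{t+1} = S Q_t S' + I

to convergence — the implicit form of diffusion on the graph whose nodes
are ordered sample pairs, never materializing the n^2 operator.

The number of clusters K is chosen by the multimodality gap: Hartigan's
dip statistic is computed for each leading eigenvector of the symmetric
normalized fused graph, and K is the position of the largest drop in dip
between consecutive eigenvectors. Samples are clustered by k-means
(kmeans++ seeding, 50 restarts) on the row-normalized leading
eigenvectors. A 2-D embedding is computed PHATE-style: row-normalize the
fused similarity to a diffusion operator, raise it to t = 200, take
Euclidean distances between the rows' negative logs (the potential
distances), and embed by metric MDS (classical solution refined by
SMACOF). Cluster read-outs follow the field's standards: a basal
composite score (sum of z-scored basal markers minus mesenchymal and
epithelial sums), pairwise Wilcoxon tests with Holm correction, and
Kaplan-Meier / log-rank survival comparisons.

The dip statistic is computed exactly, by a band-feasibility algorithm
(greatest-convex-minorant / least-concave-majorant hulls plus the
monotone join between the convex and concave branch of the fitted
unimodal CDF), and is cross-checked in the tests against an independent
linear-programming oracle.

## Worked example

```r
library(tpgfuse)

cohort <- simulate_cohort(sim_config(seed = 1))   # 360 samples, 9 subtypes
res <- analyze_cohort(
  list(expression = cohort$expression,
       methylation = cohort$methylation,
       microbiome  = cohort$microbiome),
  clinical   = cohort$clinical,
  annotation = cohort$annotation,
  cfg = run_config(seed = 1))

res$K
#> [1] 9
adjusted_rand_index(cohort$truth$subtype, res$clusters$cluster)
#> [1] 1
res$survival$global$chi2
#> [1] 63.22699
```

The selected K = 9 matches the nine planted subtypes exactly (adjusted
Rand index 1 against the generator's truth), and the global log-rank
test across the recovered clusters (chi-square 63.2 on 8 df,
p = 1.1e-10) detects the planted hazard differences (the EMT-like group
was generated with a 3x baseline hazard, the viral group with half of
it).

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01` simulates the cohorts to `results/data/`, `02` runs the
multimodal pipeline and writes the artifact bundle (similarity,
embedding, clusters, scores, differential tests, survival tables), `03`
performs the modality ablation (the hypomethylated subtype is only
isolated when methylation participates), `04` checks that the first
embedding axis orders the continuous basal-gradient cohort (Spearman
rho about 0.97 against the latent gradient), and `05` summarizes
survival. Each takes the seed as its only argument:

```sh
Rscript analysis/01_simulate_cohort.R 1
Rscript analysis/02_multimodal_clustering.R 1
```

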
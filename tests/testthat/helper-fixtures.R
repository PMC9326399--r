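# small reusable fixtures, built in code

mat_omics <- function(vals, ids = NULL, feats = NULL, modality = "expression") {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(vals)))
  if (is.null(feats)) feats <- sprintf("f%02d", seq_len(ncol(vals)))
  dimnames(vals) <- list(ids, feats)
  omics_matrix(vals, modality = modality)
}

# two well-separated Gaussian blobs, samples x features
blob_pair <- function(n_per = 10, p = 5, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p, mean = sep), n_per))
  mat_omics(x)
}

sim_matrix <- function(vals) {
  dimnames(vals) <- list(sprintf("s%02d", seq_len(nrow(vals))),
                         sprintf("s%02d", seq_len(nrow(vals))))
  similarity_matrix(vals)
}

diff_op <- function(P) {
  dimnames(P) <- list(sprintf("s%02d", seq_len(nrow(P))),
                      sprintf("s%02d", seq_len(nrow(P))))
  structure(P, t_applied = 1L, row_sums = rep(1, nrow(P)),
            class = c("diffusion_operator", "matrix", "array"))
}
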
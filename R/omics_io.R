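#' Construct an omics matrix
#'
#' The canonical in-memory container for one modality: a numeric matrix with
#' samples in rows and features in columns, carrying unique sample and feature
#' identifiers and a modality tag. All downstream math is sample-wise, so the
#' samples-by-features orientation is fixed here regardless of the on-disk
#' layout (TCGA-style files are features-by-samples).
#'
#' @param values Numeric matrix, samples x features.
#' @param sample_ids Character vector of unique sample identifiers (rows).
#' @param feature_ids Character vector of unique feature identifiers (columns).
#' @param modality One of `"expression"`, `"methylation"`, `"microbiome"`.
#' @return An object of class `omics_matrix` (a numeric matrix with dimnames
#'   and a `modality` attribute).
#' @export
omics_matrix <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values),
                         modality = c("expression", "methylation", "microbiome")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) && nrow(values) == 0L) sample_ids <- character(0)
  if (is.null(feature_ids) && ncol(values) == 0L) feature_ids <- character(0)
  if (is.null(sample_ids) || is.null(feature_ids))
    stop("sample and feature identifiers are required")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  .check_unique(sample_ids, "sample")
  .check_unique(feature_ids, "feature")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample '%s', feature '%s'",
                 sample_ids[idx[1]], feature_ids[idx[2]]))
  }
  if (modality == "methylation" && length(values) &&
      (min(values) < 0 || max(values) > 1))
    stop("methylation beta values must lie in [0, 1]")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values, modality = modality, class = c("omics_matrix", "matrix", "array"))
}

.check_unique <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(sprintf("missing %s identifier", what))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s identifiers: %s", what,
                 paste(dup, collapse = ", ")))
  invisible(TRUE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d samples x %d features\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read a modality matrix from a tab-separated file
#'
#' Expects one header row of identifiers and one leading identifier column.
#' Values are parsed as reals; any non-numeric cell or duplicate identifier is
#' an error naming the offending location.
#'
#' @param path Path to a TSV file.
#' @param orientation How the file is laid out on disk:
#'   `"features_by_samples"` (TCGA convention, the default) or
#'   `"samples_by_features"`.
#' @param modality Modality tag passed to [omics_matrix()].
#' @return An [omics_matrix()], always samples x features in memory.
#' @export
read_omics_matrix <- function(path,
                              orientation = c("features_by_samples",
                                              "samples_by_features"),
                              modality = c("expression", "methylation",
                                           "microbiome")) {
  orientation <- match.arg(orientation)
  modality <- match.arg(modality)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected an identifier column plus data columns")
  row_ids <- as.character(tab[[1]])
  col_ids <- colnames(tab)[-1]
  .check_unique(row_ids, if (orientation == "features_by_samples") "feature" else "sample")
  .check_unique(col_ids, if (orientation == "features_by_samples") "sample" else "feature")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 vals[bad[1, 1], bad[1, 2]], row_ids[bad[1, 1]],
                 col_ids[bad[1, 2]], path))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "features_by_samples") num <- t(num)
  omics_matrix(num, modality = modality)
}

#' Write a modality matrix as TSV
#'
#' Inverse of [read_omics_matrix()]: round trips are exact up to float
#' formatting (values are written with 15 significant digits).
#'
#' @param x An [omics_matrix()].
#' @param path Output path.
#' @param orientation On-disk layout to produce.
#' @export
write_omics_matrix <- function(x, path,
                               orientation = c("features_by_samples",
                                               "samples_by_features")) {
  orientation <- match.arg(orientation)
  m <- unclass(x)
  attr(m, "modality") <- NULL
  if (orientation == "features_by_samples") m <- t(m)
  id_col <- if (orientation == "features_by_samples") "feature_id" else "sample_id"
  df <- data.frame(rownames(m), signif(m, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the clinical table
#'
#' Requires columns `sample_id`, `os_months`, `os_event`; any further columns
#' are kept as categorical covariates (e.g. HPV status, tumor grade).
#'
#' @param path TSV path.
#' @return A `data.frame` of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  clinical_table(tab)
}

#' Construct/validate a clinical table
#'
#' @param df Data frame with columns `sample_id`, `os_months` (nonnegative,
#'   months), `os_event` (0/1, 1 = death observed) and optional covariates.
#' @return The validated data frame with class `clinical_table`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "os_months", "os_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  .check_unique(df$sample_id, "sample")
  df$os_months <- as.numeric(df$os_months)
  df$os_event <- as.integer(df$os_event)
  if (anyNA(df$os_months) || any(df$os_months < 0))
    stop("os_months must be nonnegative reals")
  if (anyNA(df$os_event) || !all(df$os_event %in% 0:1))
    stop("os_event must be 0/1")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a probe annotation table
#'
#' Three tab-separated columns: `probe_id`, `chromosome`, `snp_flag`
#' (logical/0-1). One record per probe.
#'
#' @param path TSV path.
#' @return Data frame with columns `probe_id`, `chromosome`, `snp_flagged`.
#' @export
read_probe_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab)[1:3] <- c("probe_id", "chromosome", "snp_flagged")
  tab$probe_id <- as.character(tab$probe_id)
  .check_unique(tab$probe_id, "probe")
  tab$snp_flagged <- as.logical(tab$snp_flagged)
  tab
}

#' Restrict matched modalities and clinical data to common samples
#'
#' Intersects sample identifiers across all matrices and the clinical table
#' and reorders every output to one canonical (lexicographic) order, so that
#' row i refers to the same sample everywhere downstream.
#'
#' @param matrices List of [omics_matrix()] objects (at least two).
#' @param clinical Optional `clinical_table`.
#' @return List with elements `matrices` (same length, aligned) and
#'   `clinical` (aligned, or `NULL`).
#' @export
align_samples <- function(matrices, clinical = NULL) {
  if (!is.list(matrices) || length(matrices) < 1)
    stop("need a list of omics matrices")
  ids <- Reduce(intersect, lapply(matrices, rownames))
  if (!is.null(clinical)) ids <- intersect(ids, clinical$sample_id)
  if (length(ids) == 0) stop("no samples shared across inputs")
  ids <- sort(ids)
  out <- lapply(matrices, function(m) {
    omics_matrix(unclass(m)[ids, , drop = FALSE], modality = attr(m, "modality"))
  })
  clin <- NULL
  if (!is.null(clinical)) {
    clin <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
    rownames(clin) <- NULL
    class(clin) <- c("clinical_table", "data.frame")
  }
  list(matrices = out, clinical = clin)
}

#' Filter methylation probes by SNP flag and sex chromosome
#'
#' Retains exactly the probes annotated `snp_flagged = FALSE` and with
#' chromosome outside X/Y, preserving the original probe order. Probes absent
#' from the annotation are handled by `missing_policy`: dropped with a logged
#' count (default) or an error.
#'
#' @param meth Methylation [omics_matrix()].
#' @param annotation Data frame as returned by [read_probe_annotation()].
#' @param missing_policy `"drop"` (default, with warning) or `"error"`.
#' @return Filtered methylation [omics_matrix()].
#' @export
filter_probes <- function(meth, annotation, missing_policy = c("drop", "error")) {
  missing_policy <- match.arg(missing_policy)
  if (attr(meth, "modality") != "methylation")
    stop("filter_probes expects the methylation modality")
  probes <- colnames(meth)
  idx <- match(probes, annotation$probe_id)
  absent <- is.na(idx)
  if (any(absent)) {
    if (missing_policy == "error")
      stop(sprintf("%d probes absent from annotation (first: %s)",
                   sum(absent), probes[which(absent)[1]]))
    warning(sprintf("dropping %d probes absent from annotation", sum(absent)))
  }
  keep <- !absent
  keep[keep] <- !annotation$snp_flagged[idx[keep]] &
    !(toupper(sub("^CHR", "", toupper(annotation$chromosome[idx[keep]]))) %in% c("X", "Y"))
  out <- unclass(meth)[, keep, drop = FALSE]
  omics_matrix(out, modality = "methylation")
}

#' Z-score features across samples
#'
#' Centers and scales every feature column to mean 0, sd 1 (sample sd, n-1),
#' the same convention as base `scale()`. Zero-variance features are set to
#' all-zero and their count reported via message.
#'
#' @param m An [omics_matrix()].
#' @return An expression-tagged [omics_matrix()] of z-scores (modality kept).
#' @export
zscore_features <- function(m) {
  if (nrow(m) < 2) stop("z-scoring needs at least two samples")
  vals <- unclass(m)
  sc <- scale(vals)
  sds <- attr(sc, "scaled:scale")
  zero <- !is.finite(sds) | sds == 0
  if (any(zero)) {
    sc[, zero] <- 0
    message(sprintf("zscore_features: %d zero-variance features set to 0",
                    sum(zero)))
  }
  out <- matrix(as.numeric(sc), nrow(vals), ncol(vals),
                dimnames = dimnames(vals))
  modality <- attr(m, "modality")
  if (modality == "methylation") {
    # z-scores leave [0,1]; keep the data but tag as expression-like scale
    structure(out, modality = "methylation",
              class = c("omics_matrix", "matrix", "array"))
  } else {
    omics_matrix(out, modality = modality)
  }
}
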
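test_that("matrix round trip preserves values and orientation contract", {
  vals <- matrix(c(1.5, -2.25, 3, 0.125, 7, -0.5), nrow = 3,
                 dimnames = list(c("sA", "sB", "sC"), c("g1", "g2")))
  m <- omics_matrix(vals, modality = "expression")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(m, tf, orientation = "features_by_samples")
  back <- read_omics_matrix(tf, orientation = "features_by_samples",
                            modality = "expression")
  expect_equal(unclass(back), unclass(m), tolerance = 1e-9)
  expect_identical(rownames(back), c("sA", "sB", "sC"))

  # a features-by-samples file with 4 features, 2 samples reads as 2 x 4
  tab <- data.frame(feature_id = paste0("f", 1:4),
                    sA = 1:4, sB = 5:8)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  m2 <- read_omics_matrix(tf2, "features_by_samples", "expression")
  expect_identical(dim(m2), c(2L, 4L))
  expect_identical(colnames(m2), paste0("f", 1:4))
})

test_that("duplicate identifiers and bad cells are reported by location", {
  tab <- data.frame(feature_id = c("f1", "f2"), sA = c(1, 2), sA = c(3, 4),
                    check.names = FALSE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_omics_matrix(tf, "features_by_samples", "expression"),
               "sA")

  tab2 <- data.frame(feature_id = c("f1", "f2"), sA = c("1.5", "oops"))
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab2, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_omics_matrix(tf2, "features_by_samples", "expression"),
               "oops")

  expect_error(omics_matrix(matrix(c(0.5, 1.2), 1, 2,
                                   dimnames = list("s", c("p1", "p2"))),
                            modality = "methylation"),
               "\\[0, 1\\]")
  expect_error(mat_omics(matrix(c(1, NA), 1, 2)), "missing value")
})

test_that("align_samples intersects, orders canonically, and is idempotent", {
  m1 <- mat_omics(matrix(1:6, 3, 2), ids = c("A", "B", "C"))
  m2 <- mat_omics(matrix((1:6) / 10, 3, 2), ids = c("B", "C", "D"),
                  modality = "methylation")
  m3 <- mat_omics(matrix(1:4, 2, 2), ids = c("C", "B"),
                  modality = "microbiome")
  al <- align_samples(list(m1, m2, m3))
  for (m in al$matrices) expect_identical(rownames(m), c("B", "C"))
  # row i refers to the same sample: values follow the reordering
  expect_equal(al$matrices[[3]]["B", ], m3["B", ])
  # idempotent
  al2 <- align_samples(al$matrices)
  expect_identical(lapply(al2$matrices, unclass), lapply(al$matrices, unclass))
  # commutes with list order
  al3 <- align_samples(list(m3, m1, m2))
  expect_identical(unclass(al3$matrices[[2]]), unclass(al$matrices[[1]]))

  m4 <- mat_omics(matrix(1:4, 2, 2), ids = c("X", "Y"))
  expect_error(align_samples(list(m1, m4)), "no samples shared")

  clin <- clinical_table(data.frame(sample_id = c("C", "B", "A"),
                                    os_months = c(5, 10, 1),
                                    os_event = c(1, 0, 1)))
  al4 <- align_samples(list(m1, m2), clin)
  expect_identical(al4$clinical$sample_id, c("B", "C"))
  expect_identical(al4$clinical$os_months, c(10, 5))
})

test_that("filter_probes keeps exactly unflagged autosomal probes, in order", {
  meth <- mat_omics(matrix(runif(10), 2, 5), modality = "methylation")
  ann <- data.frame(probe_id = paste0("f0", 1:5),
                    chromosome = c("1", "X", "7", "Y", "12"),
                    snp_flagged = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- filter_probes(meth, ann)
  expect_identical(colnames(out), c("f01", "f05"))
  # brute-force set comprehension agrees
  keep <- ann$probe_id[!ann$snp_flagged & !(ann$chromosome %in% c("X", "Y"))]
  expect_setequal(colnames(out), keep)

  # nothing flagged: identity
  ann2 <- data.frame(probe_id = paste0("f0", 1:5), chromosome = "2",
                     snp_flagged = FALSE)
  expect_equal(unclass(filter_probes(meth, ann2)), unclass(meth))

  # everything flagged: empty matrix, downstream use fails
  ann3 <- transform(ann2, snp_flagged = TRUE)
  empty <- filter_probes(meth, ann3)
  expect_identical(ncol(empty), 0L)
  expect_error(pairwise_distance(empty))

  # unknown probes: default drop with warning, error policy available
  ann4 <- ann2[1:3, ]
  expect_warning(out4 <- filter_probes(meth, ann4), "dropping 2")
  expect_identical(colnames(out4), paste0("f0", 1:3))
  expect_error(filter_probes(meth, ann4, missing_policy = "error"), "absent")
})

test_that("zscore_features matches base scale(), zero-variance to zero", {
  m <- mat_omics(cbind(c(1, 2, 3), c(5, 5, 5)))
  expect_message(z <- zscore_features(m), "zero-variance")
  expect_equal(unname(z[, 1]), c(-1, 0, 1))
  expect_identical(unname(z[, 2]), c(0, 0, 0))
  # idempotence on an already-standardized column
  z1 <- mat_omics(unclass(z)[, 1, drop = FALSE])
  z2 <- zscore_features(z1)
  expect_equal(unclass(z2), unclass(z1), tolerance = 1e-12)
})
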
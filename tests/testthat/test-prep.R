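raw_dense <- function(values, ...) {
  pcasketch:::new_raw_matrix(values, ...)
}

test_that("log2 with pseudocount 1 maps powers of two exactly", {
  raw <- raw_dense(matrix(c(0, 3, 1, 7), 2, 2),
                   orientation = "samples_by_features")
  prep <- prep_matrix(raw, log_base = 2, pseudocount = 1)
  expect_equal(prep$values, matrix(c(0, 2, 1, 3), 2, 2), ignore_attr = TRUE)
  expect_identical(prep$provenance$log_base, 2)
  expect_false(prep$provenance$centered)
})

test_that("center + scale uses the n-1 sample standard deviation", {
  raw <- raw_dense(matrix(c(1, 2, 3), ncol = 1),
                   orientation = "samples_by_features")
  prep <- prep_matrix(raw, center = TRUE, scale = TRUE)
  expect_equal(as.numeric(prep$values), c(-1, 0, 1))
  expect_equal(prep$col_means, 2, ignore_attr = TRUE)
  expect_equal(prep$col_sds, 1, ignore_attr = TRUE)
})

test_that("features-by-samples input is transposed, names following", {
  counts <- make_counts(n_cells = 40, n_genes = 12, seed = 3)
  prep <- prep_matrix(counts)
  expect_equal(dim(prep$values), c(40L, 12L))
  expect_identical(prep$sample_ids[1L], "cell_0001")
  expect_identical(prep$feature_ids[1L], "gene_0001")
  expect_true(prep$provenance$transposed)
})

test_that("orientation auto-detection treats the longer axis as samples", {
  tall <- raw_dense(matrix(1:60 + 0.5, 20, 3))   # 20 > 3: rows are samples
  expect_false(prep_matrix(tall)$provenance$transposed)
  wide <- raw_dense(matrix(1:60 + 0.5, 3, 20))   # 3 < 20: columns are samples
  expect_true(prep_matrix(wide)$provenance$transposed)
  sq <- raw_dense(matrix(rnorm(16), 4, 4))
  expect_error(prep_matrix(sq), "orientation ambiguous")
  # explicit declaration overrides size-based guessing
  expect_true(prep_matrix(sq, orientation = "features_by_samples")$provenance$transposed)
})

test_that("zero-variance features follow the configured policy", {
  vals <- cbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(2, 1, 4, 3))
  raw <- raw_dense(vals, col_names = c("a", "const", "b"),
                   orientation = "samples_by_features")
  expect_warning(drop <- prep_matrix(raw, center = TRUE, scale = TRUE), "zero-variance")
  expect_equal(ncol(drop$values), 2L)
  expect_identical(drop$provenance$dropped_features, "const")
  expect_identical(drop$feature_ids, c("a", "b"))

  keep <- prep_matrix(raw, center = TRUE, scale = TRUE,
                      zero_variance_policy = "keep_zero")
  expect_equal(ncol(keep$values), 3L)
  expect_equal(keep$values[, 2L], rep(0, 4))

  expect_error(prep_matrix(raw, center = TRUE, scale = TRUE,
                           zero_variance_policy = "error"),
               "zero variance feature")
  # without scaling a constant feature is harmless and kept as-is
  expect_equal(ncol(prep_matrix(raw, center = TRUE)$values), 3L)
})

test_that("log transform preconditions are enforced", {
  neg <- raw_dense(matrix(c(-1, 2, 3, 4), 2, 2),
                   orientation = "samples_by_features")
  expect_error(prep_matrix(neg, log_base = 2), "negative values under log")
  zeros <- raw_dense(matrix(c(0, 2, 3, 4), 2, 2),
                     orientation = "samples_by_features")
  expect_error(prep_matrix(zeros, log_base = 2, pseudocount = 0), "pseudocount")
})

test_that("prep without transforms is a densifying identity, and prep is deterministic", {
  counts <- make_counts(n_cells = 25, n_genes = 8, seed = 9)
  plain <- prep_matrix(counts, orientation = "samples_by_features")
  expect_identical(plain$values, as.matrix(counts$values))

  a <- prep_matrix(counts, log_base = 2, center = TRUE, scale = TRUE)
  b <- prep_matrix(counts, log_base = 2, center = TRUE, scale = TRUE)
  expect_identical(a$values, b$values)
})

test_that("centered+scaled output has the expected total sum of squares", {
  counts <- make_counts(n_cells = 60, n_genes = 15, seed = 21)
  prep <- prep_matrix(counts, log_base = 2, center = TRUE, scale = TRUE)
  n <- nrow(prep$values); p <- ncol(prep$values)
  expect_equal(sum(prep$values^2), (n - 1) * p, tolerance = 1e-6)
  expect_lt(max(abs(colMeans(prep$values))), 1e-8)
  expect_lt(max(abs(apply(prep$values, 2, sd) - 1)), 1e-8)
})
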
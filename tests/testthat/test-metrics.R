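test_that("reconstruction satisfies the Eckart-Young spectral identity", {
  M <- seeded_matrix(10, 6, seed = 31)
  full <- exact_svd(M)
  expect_lt(sqrt(sum((reconstruct(full) - M)^2)), 1e-10 * sqrt(sum(M^2)))
  for (k in 1:5) {
    err <- sqrt(sum((M - reconstruct(full, k))^2))
    expect_lt(abs(err - sqrt(sum(full$S[(k + 1):full$k]^2))) / err, 1e-8)
  }
  expect_error(reconstruct(full, 0), "invalid rank")
  expect_error(reconstruct(truncate_svd(full, 2), 3), "insufficient components")
})

test_that("sse_ratio is 1 for the truncated reference and > 1 for anything else", {
  M <- seeded_matrix(30, 15, seed = 37)
  ex <- exact_svd(M)
  k <- 5
  expect_equal(sse_ratio(truncate_svd(ex, k), ex, M, k), 1.0)

  # an arbitrary rank-k orthonormal basis is strictly suboptimal
  b <- resolve_backend()
  Q <- qr.Q(qr(b$gaussian(30, k, seed = 1)))
  B <- t(Q) %*% M
  sm <- svd(B)
  cand <- pcasketch:::new_svd_result(Q %*% sm$u, sm$d, t(sm$v), k,
                                     "randomized", "reference")
  expect_gt(sse_ratio(cand, ex, M, k), 1)

  r <- randomized_svd(M, k = k, oversample = 3, power_iters = 0, seed = 3)
  expect_gte(sse_ratio(r, ex, M, k), 1 - 1e-8)

  expect_error(sse_ratio(r, r, M, k), "reference must come")
  # a matrix of exact rank k has zero reference SSE: the ratio is undefined
  D <- diag(c(3, 2, 0))
  ex2 <- exact_svd(D)
  expect_error(sse_ratio(truncate_svd(ex2, 2), ex2, D, 2),
               "reference SSE is zero")
})

test_that("frobenius_error reports both norms and handles degenerate input", {
  tr <- make_lowrank(20, 10, spectrum = c(6, 4, 2, 1), noise_sd = 0, seed = 41)
  ex <- exact_svd(tr$matrix)
  fe <- frobenius_error(tr$matrix, ex, k = 2)
  expect_equal(fe$absolute, sqrt(sum(ex$S[3:ex$k]^2)), tolerance = 1e-8)
  expect_equal(fe$relative, fe$absolute / sqrt(sum(tr$matrix^2)),
               tolerance = 1e-12)
  expect_identical(fe$divisor, "frobenius")

  fe_c <- frobenius_error(tr$matrix, ex, k = 2, divisor = "centered_rss")
  expect_identical(fe_c$divisor, "centered_rss")
  expect_gt(fe_c$relative, fe$relative)  # centered divisor is never larger

  zed <- exact_svd(matrix(0, 3, 3))
  z <- frobenius_error(matrix(0, 3, 3), zed)
  expect_equal(z$absolute, 0)
  expect_equal(z$relative, 0)
})

test_that("ccc reproduces Lin's closed forms and its bounds", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1.0, tolerance = 1e-15)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1.0, tolerance = 1e-15)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-15)
  expect_error(ccc(1:3, 1:4), "length mismatch")
  expect_error(ccc(c(2, 2, 2), c(2, 2, 2)), "CCC undefined")

  set.seed(53)
  for (i in 1:20) {
    x <- rnorm(30)
    y <- rnorm(30, mean = 0.3)
    expect_equal(ccc(x, x), 1.0, tolerance = 1e-15)
    expect_lt(ccc(x, x + 0.5), 1)
    expect_lte(abs(ccc(x, y)), abs(stats::cor(x, y)) + 1e-12)
  }
})

test_that("align_signs undoes arbitrary per-component flips and is idempotent", {
  M <- seeded_matrix(18, 9, seed = 59)
  ref <- exact_svd(M, k = 6)
  flips <- c(1, -1, 1, -1, -1, 1)
  cand <- ref
  cand$U <- sweep(ref$U, 2, flips, "*")
  cand$Vt <- sweep(ref$Vt, 1, flips, "*")
  aligned <- align_signs(cand, ref)
  expect_equal(aligned$U, ref$U)
  expect_equal(aligned$Vt, ref$Vt)
  expect_identical(aligned$S, ref$S)
  expect_identical(align_signs(aligned, ref), aligned)
  expect_identical(align_signs(ref, ref), ref)
  expect_error(align_signs(truncate_svd(ref, 2), ref), "shape mismatch")
})

test_that("compare_decompositions bundles the agreement statistics coherently", {
  M <- seeded_matrix(40, 20, seed = 61)
  ex <- exact_svd(M)
  k <- 8
  trivial <- compare_decompositions(truncate_svd(ex, k), ex, M, k)
  expect_equal(trivial$sse_ratio, 1.0)
  expect_equal(trivial$ccc_singular_values, 1.0, tolerance = 1e-15)
  expect_equal(unname(trivial$ccc_pc), c(1, 1), tolerance = 1e-15)

  tr <- make_lowrank(100, 40, spectrum = c(20, 12, 8, 5, 3, 2, 1, 0.5),
                     noise_sd = 0.05, seed = 67)
  ratios <- cccs <- numeric(20)
  for (s in 1:20) {
    exs <- exact_svd(tr$matrix)
    rs <- randomized_svd(tr$matrix, k = 8, seed = s)
    rep <- compare_decompositions(rs, exs, tr$matrix, 8)
    ratios[s] <- rep$sse_ratio
    cccs[s] <- rep$ccc_singular_values
  }
  expect_lt(stats::median(ratios), 1.05)
  expect_gte(stats::median(ratios), 1 - 1e-8)
  expect_gt(stats::median(cccs), 0.999)
})
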
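test_that("exact SVD handles canonical small cases", {
  s <- exact_svd(diag(c(3, 2)))
  expect_equal(s$S, c(3, 2))
  expect_equal(abs(s$U), diag(2), tolerance = 1e-12)
  expect_equal(abs(s$Vt), diag(2), tolerance = 1e-12)

  z <- exact_svd(matrix(0, 4, 3))
  expect_equal(z$S, c(0, 0, 0))

  expect_error(exact_svd(matrix(c(1, NA, 2, 3), 2, 2)), "invalid matrix")
  expect_error(exact_svd(diag(3), k = 5), "invalid rank")
})

test_that("exact singular values agree with the normal-equations oracle", {
  for (seed in 1:10) {
    M <- seeded_matrix(6 * seed %% 30 + 10, 4 * seed %% 20 + 8, seed)
    s <- exact_svd(M)
    oracle <- normal_equations_singular_values(M)
    expect_lt(max_rel_diff(s$S, oracle), 1e-9)
  }
})

test_that("exact decomposition factors are orthonormal and reconstruct M", {
  M <- seeded_matrix(25, 12, seed = 7)
  s <- exact_svd(M)
  expect_lt(max(abs(crossprod(s$U) - diag(s$k))), 1e-8)
  expect_lt(max(abs(tcrossprod(s$Vt) - diag(s$k))), 1e-8)
  expect_lt(sqrt(sum((reconstruct(s) - M)^2)), 1e-10 * sqrt(sum(M^2)))
  # the sign convention pins each U column's largest-|entry| to positive
  for (i in seq_len(s$k)) expect_gt(s$U[which.max(abs(s$U[, i])), i], 0)
})

test_that("randomized SVD is exact when the sketch covers the rank", {
  u <- c(3, 4) / 5
  v <- c(1, 2, 2) / 3
  r1 <- randomized_svd(5 * tcrossprod(u, v), k = 1, oversample = 1, seed = 2)
  expect_equal(r1$S, 5, tolerance = 1e-8)

  ident <- randomized_svd(diag(10), k = 3, seed = 4)
  expect_equal(ident$S, c(1, 1, 1), tolerance = 1e-8)
})

test_that("randomized singular values track the exact ones and never exceed them", {
  tr <- make_lowrank(80, 40, spectrum = c(10, 5, 2, 1), noise_sd = 0.01, seed = 6)
  ex <- exact_svd(tr$matrix)
  rs <- randomized_svd(tr$matrix, k = 4, oversample = 10, power_iters = 4, seed = 6)
  expect_lt(max_rel_diff(rs$S, ex$S[1:4]), 1e-6)
  # projection onto a k+p subspace can only shrink singular values
  for (seed in 1:5) {
    M <- seeded_matrix(40, 25, seed)
    r <- randomized_svd(M, k = 8, oversample = 4, power_iters = 0, seed = seed)
    expect_true(all(r$S <= exact_svd(M, k = 8)$S + 1e-8))
  }
})

test_that("randomized SVD is bit-reproducible for a fixed seed and sensitive to it", {
  M <- seeded_matrix(50, 30, seed = 13)
  a <- randomized_svd(M, k = 5, seed = 42)
  b <- randomized_svd(M, k = 5, seed = 42)
  expect_identical(a$U, b$U)
  expect_identical(a$S, b$S)
  expect_identical(a$Vt, b$Vt)
  expect_false(identical(a$U, randomized_svd(M, k = 5, seed = 43)$U))
})

test_that("sketch-width and rank preconditions are enforced", {
  M <- seeded_matrix(20, 10, seed = 1)
  expect_error(randomized_svd(M, k = 5, oversample = 6), "sketch width")
  expect_error(randomized_svd(M, k = 0), "invalid rank")
})

test_that("more power iterations never worsen reconstruction of a noisy low-rank matrix", {
  sse_at <- function(q, seed) {
    tr <- make_lowrank(60, 30, spectrum = c(8, 6, 5, 4, 3), noise_sd = 0.5,
                       seed = seed)
    r <- randomized_svd(tr$matrix, k = 5, oversample = 2, power_iters = q,
                        seed = seed)
    sum((tr$matrix - reconstruct(r))^2)
  }
  for (q in c(1, 2, 4)) {
    deltas <- vapply(1:20, function(s) sse_at(0, s) - sse_at(q, s), numeric(1))
    expect_gte(stats::median(deltas), -1e-10)
  }
})

test_that("truncation keeps leading triplets and refuses to extend", {
  M <- seeded_matrix(6, 4, seed = 8)
  full <- exact_svd(M)
  expect_identical(truncate_svd(full, 4), full)
  t2 <- truncate_svd(full, 2)
  expect_identical(t2$S, full$S[1:2])
  expect_identical(t2$U, full$U[, 1:2])
  expect_identical(t2$method, "exact")
  expect_error(truncate_svd(t2, 3), "cannot extend")
  expect_error(truncate_svd(full, 0), "invalid rank")
})
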
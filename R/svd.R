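# Exact and randomized truncated SVD. The exact path computes the full
# decomposition and truncates; the randomized path is the Halko-family
# Gaussian sketch with QR-stabilized power iteration. Both apply the same
# deterministic sign convention so components are directly comparable.

new_svd_result <- function(U, S, Vt, k, method, backend_name,
                           seed = NULL, oversample = NULL, power_iters = NULL) {
  structure(
    list(U = U, S = S, Vt = Vt, k = k, method = method,
         backend_name = backend_name, seed = seed,
         oversample = oversample, power_iters = power_iters),
    class = "svd_result"
  )
}

#' @export
print.svd_result <- function(x, ...) {
  cat("<svd_result> method=", x$method, " k=", x$k,
      " | U: ", nrow(x$U), "x", ncol(x$U),
      " | leading S: ", paste(signif(utils::head(x$S, 4L), 5L), collapse = ", "),
      if (x$k > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Deterministic sign convention: flip each (U column, Vt row) pair so the
# entry of largest absolute value in the U column is positive. An all-zero
# column (zero singular value) is left untouched.
apply_sign_convention <- function(U, Vt) {
  for (i in seq_len(ncol(U))) {
    j <- which.max(abs(U[, i]))
    if (U[j, i] < 0) {
      U[, i] <- -U[, i]
      Vt[i, ] <- -Vt[i, ]
    }
  }
  list(U = U, Vt = Vt)
}

.as_values <- function(M) {
  if (inherits(M, "prepared_matrix")) M$values else as.matrix(M)
}

#' Exact (full) singular value decomposition, truncated to k
#'
#' Computes the complete SVD of the dense matrix and keeps the leading `k`
#' triplets. Intended as the reference decomposition that truncated and
#' randomized methods are validated against; for large matrices prefer
#' [randomized_svd()].
#'
#' @param M A `prepared_matrix` or plain numeric matrix (samples x features).
#' @param k Number of components to retain; default `min(dim(M))` (all).
#' @param backend A backend handle from [resolve_backend()]; default the
#'   reference backend.
#' @return An `svd_result` with `U` (samples x k), non-increasing
#'   non-negative `S` (length k), and `Vt` (k x features).
#' @examples
#' s <- exact_svd(diag(c(3, 2)))
#' s$S  # 3 2
#' @export
exact_svd <- function(M, k = NULL, backend = resolve_backend()) {
  M <- .as_values(M)
  if (!all(is.finite(M))) stop("invalid matrix: non-finite entries")
  r <- min(dim(M))
  if (is.null(k)) k <- r
  k <- .check_rank(k, r)
  d <- backend$svd_small(M)
  U <- d$u[, seq_len(k), drop = FALSE]
  S <- d$d[seq_len(k)]
  Vt <- d$vt[seq_len(k), , drop = FALSE]
  fl <- apply_sign_convention(U, Vt)
  new_svd_result(fl$U, S, fl$Vt, k, "exact", backend$name)
}

.check_rank <- function(k, r) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("invalid rank: k must be a positive integer")
  }
  k <- as.integer(k)
  if (k > r) stop("invalid rank: k = ", k, " exceeds min(dim) = ", r)
  k
}

#' Randomized truncated SVD (Gaussian sketch with power iteration)
#'
#' Draws a seeded Gaussian test matrix of width `k + oversample`, sketches
#' the range of `M`, sharpens it with `power_iters` rounds of subspace
#' iteration (re-orthonormalizing by QR at every half-step for numerical
#' stability), then takes the exact SVD of the small projected matrix
#' `B = Q'M`. Results are bit-reproducible for a fixed (backend, seed) pair.
#'
#' @param M A `prepared_matrix` or numeric matrix (samples x features).
#' @param k Target rank (number of components returned).
#' @param oversample Extra sketch columns beyond `k`; `NULL` (default) uses
#'   `min(10, min(dim(M)) - k)`, i.e. 10 unless the matrix is too small to
#'   afford them. An explicit value that pushes the sketch past
#'   `min(dim(M))` is an error.
#' @param power_iters Power-iteration rounds; default 2. More iterations
#'   sharpen the captured subspace when the spectrum decays slowly.
#' @param seed Integer seed for the Gaussian test matrix.
#' @param backend Backend handle from [resolve_backend()].
#' @return An `svd_result` with `method = "randomized"`; each approximate
#'   singular value is bounded above by its exact counterpart.
#' @examples
#' m <- make_lowrank(40, 20, spectrum = c(5, 2), noise_sd = 0, seed = 1)$matrix
#' randomized_svd(m, k = 2, seed = 1)$S  # ~ 5 2
#' @export
randomized_svd <- function(M, k, oversample = NULL, power_iters = 2L,
                           seed = 1L, backend = resolve_backend()) {
  M <- .as_values(M)
  if (!all(is.finite(M))) stop("invalid matrix: non-finite entries")
  r <- min(dim(M))
  k <- .check_rank(k, r)
  if (is.null(oversample)) oversample <- min(10L, r - k)
  oversample <- as.integer(oversample)
  power_iters <- as.integer(power_iters)
  stopifnot(oversample >= 0L, power_iters >= 0L)
  l <- k + oversample
  if (l > r) {
    stop("sketch width exceeds rank bound: k + oversample = ", l,
         " > min(dim) = ", r)
  }
  seed <- as.integer(seed)

  Omega <- backend$gaussian(ncol(M), l, seed)
  Y <- backend$matmul(M, Omega)
  Q <- backend$qr(Y)$Q
  for (i in seq_len(power_iters)) {
    Z <- backend$qr(backend$matmul(t(M), Q))$Q
    Q <- backend$qr(backend$matmul(M, Z))$Q
  }
  B <- backend$matmul(t(Q), M)
  d <- backend$svd_small(B)
  U <- backend$matmul(Q, d$u[, seq_len(k), drop = FALSE])
  S <- d$d[seq_len(k)]
  Vt <- d$vt[seq_len(k), , drop = FALSE]
  fl <- apply_sign_convention(U, Vt)
  new_svd_result(fl$U, S, fl$Vt, k, "randomized", backend$name,
                 seed = seed, oversample = oversample,
                 power_iters = power_iters)
}

#' Truncate an existing decomposition to fewer components
#'
#' @param result An `svd_result`.
#' @param k_new New rank, at most `result$k`.
#' @return The `svd_result` restricted to its first `k_new` triplets; method
#'   and backend metadata preserved.
#' @export
truncate_svd <- function(result, k_new) {
  stopifnot(inherits(result, "svd_result"))
  k_new <- .check_rank(k_new, min(nrow(result$U), ncol(result$Vt)))
  if (k_new > result$k) {
    stop("cannot extend truncation: k_new = ", k_new, " > k = ", result$k)
  }
  idx <- seq_len(k_new)
  new_svd_result(result$U[, idx, drop = FALSE], result$S[idx],
                 result$Vt[idx, , drop = FALSE], k_new, result$method,
                 result$backend_name, result$seed, result$oversample,
                 result$power_iters)
}
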
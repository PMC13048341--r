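# Validation statistics for comparing a candidate truncated decomposition
# against the exact reference of the same matrix: low-rank reconstruction,
# sum-of-squares-error ratio (Eckart-Young-normalized), Frobenius errors,
# Lin's concordance correlation coefficient, and sign alignment.

#' Rank-k reconstruction from a decomposition
#'
#' @param svd An `svd_result`.
#' @param k Components to use; default all available.
#' @return The matrix `U[, 1:k] %*% diag(S[1:k]) %*% Vt[1:k, ]`.
#' @export
reconstruct <- function(svd, k = NULL) {
  stopifnot(inherits(svd, "svd_result"))
  if (is.null(k)) k <- svd$k
  k <- as.integer(k)
  if (k < 1L) stop("invalid rank: k must be >= 1")
  if (k > svd$k) {
    stop("insufficient components: requested ", k, ", decomposition has ", svd$k)
  }
  idx <- seq_len(k)
  # U * diag(S) * Vt without forming diag()
  (svd$U[, idx, drop = FALSE] * rep(svd$S[idx], each = nrow(svd$U))) %*%
    svd$Vt[idx, , drop = FALSE]
}

frob <- function(M) sqrt(sum(M^2))

#' Sum-of-squares-error ratio against the exact truncated reference
#'
#' `||M - reconstruct(candidate, k)||_F^2 / ||M - reconstruct(exact, k)||_F^2`.
#' By the Eckart-Young theorem the exact rank-k truncation is the optimal
#' rank-k approximation in Frobenius norm, so the ratio is >= 1 (up to
#' floating-point slack); 1 means the candidate captures the same variance
#' as the optimal truncation, and the excess over 1 quantifies the
#' candidate's extra reconstruction error.
#'
#' @param candidate Candidate `svd_result` (e.g. randomized).
#' @param reference_exact Exact `svd_result` of the same matrix, covering at
#'   least `k` components.
#' @param M The matrix both decompositions factored.
#' @param k Comparison rank.
#' @return A single number >= 1 - 1e-8.
#' @export
sse_ratio <- function(candidate, reference_exact, M, k) {
  stopifnot(inherits(candidate, "svd_result"),
            inherits(reference_exact, "svd_result"))
  if (!identical(reference_exact$method, "exact")) {
    stop("reference must come from exact_svd()")
  }
  M <- .as_values(M)
  if (!identical(dim(M), c(nrow(candidate$U), ncol(candidate$Vt)))) {
    stop("shape mismatch between M and candidate decomposition")
  }
  sse_cand <- sum((M - reconstruct(candidate, k))^2)
  sse_ref <- sum((M - reconstruct(reference_exact, k))^2)
  if (sse_ref < 1e-300) {
    stop("reference SSE is zero: M has rank <= ", k,
         "; the ratio is undefined")
  }
  sse_cand / sse_ref
}

#' Frobenius reconstruction error, absolute and relative
#'
#' Absolute error is `||M - reconstruct(svd, k)||_F`; relative error divides
#' by `||M||_F` (default) or by the square root of the total centered sum of
#' squares (`divisor = "centered_rss"`), the divisor being recorded in the
#' result for transparency.
#'
#' @param M The original matrix.
#' @param svd Its decomposition.
#' @param k Rank at which to reconstruct; default all components of `svd`.
#' @param divisor `"frobenius"` or `"centered_rss"`.
#' @return A list with `absolute`, `relative`, and `divisor`.
#' @export
frobenius_error <- function(M, svd, k = NULL,
                            divisor = c("frobenius", "centered_rss")) {
  divisor <- match.arg(divisor)
  M <- .as_values(M)
  R <- reconstruct(svd, k)
  if (!identical(dim(M), dim(R))) stop("shape mismatch")
  absolute <- frob(M - R)
  denom <- switch(divisor,
    frobenius = frob(M),
    centered_rss = sqrt(sum(sweep(M, 2L, colMeans(M), "-")^2))
  )
  if (denom == 0) {
    if (absolute == 0) {
      relative <- 0
    } else {
      warning("zero-norm original matrix; relative error is infinite")
      relative <- Inf
    }
  } else {
    relative <- absolute / denom
  }
  list(absolute = absolute, relative = relative, divisor = divisor)
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moment estimators, per Lin's original definition. Unlike
#' the Pearson correlation it penalizes location and scale shifts: it is 1
#' only when `y` equals `x` elementwise.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return A number in `[-1, 1]`.
#' @examples
#' ccc(1:3, 1:3)     # 1
#' ccc(1:3, 2:4)     # 4/7
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("CCC undefined: both vectors constant and equal")
  2 * sxy / denom
}

#' Align the signs of a candidate decomposition to a reference
#'
#' SVD component signs are arbitrary: `(u, v)` and `(-u, -v)` describe the
#' same triplet. Before comparing singular vectors or PC scores between two
#' decompositions, each candidate (U column, Vt row) pair is negated iff its
#' U column points away from the reference's (negative dot product).
#' Idempotent; singular values untouched.
#'
#' @param candidate,reference `svd_result` objects with identical shapes.
#' @return The candidate with aligned signs.
#' @export
align_signs <- function(candidate, reference) {
  stopifnot(inherits(candidate, "svd_result"), inherits(reference, "svd_result"))
  if (!identical(dim(candidate$U), dim(reference$U)) ||
      !identical(dim(candidate$Vt), dim(reference$Vt))) {
    stop("shape mismatch between candidate and reference")
  }
  U <- candidate$U
  Vt <- candidate$Vt
  for (i in seq_len(ncol(U))) {
    if (sum(U[, i] * reference$U[, i]) < 0) {
      U[, i] <- -U[, i]
      Vt[i, ] <- -Vt[i, ]
    }
  }
  out <- candidate
  out$U <- U
  out$Vt <- Vt
  out
}

#' Bundle the full comparison of a candidate against the exact reference
#'
#' Computes, at rank `k`: the SSE ratio, the CCC over the first `k` singular
#' values, the CCC of each of the first `n_pcs_to_compare` PC score vectors
#' (after sign alignment), and the Frobenius errors of the candidate's
#' rank-k reconstruction.
#'
#' @param candidate Candidate `svd_result`.
#' @param reference_exact Exact reference `svd_result` of the same matrix.
#' @param M The matrix both decomposed.
#' @param k Comparison rank.
#' @param n_pcs_to_compare How many leading PC score vectors get a CCC
#'   (default 2, the usual visualization axes).
#' @return A `metrics_report` list: `sse_ratio`, `ccc_singular_values`,
#'   `ccc_pc` (named vector), `absolute_error`, `relative_error`, `k`.
#' @export
compare_decompositions <- function(candidate, reference_exact, M, k,
                                   n_pcs_to_compare = 2L) {
  M <- .as_values(M)
  ratio <- sse_ratio(candidate, reference_exact, M, k)
  idx <- seq_len(k)
  ccc_sv <- ccc(candidate$S[idx], reference_exact$S[idx])
  cand_trunc <- truncate_svd(candidate, k)
  ref_trunc <- truncate_svd(reference_exact, k)
  aligned <- align_signs(cand_trunc, ref_trunc)
  n_pcs <- min(as.integer(n_pcs_to_compare), k)
  ccc_pc <- vapply(seq_len(n_pcs), function(i) {
    ccc(aligned$U[, i] * aligned$S[i], ref_trunc$U[, i] * ref_trunc$S[i])
  }, numeric(1L))
  names(ccc_pc) <- paste0("PC", seq_len(n_pcs))
  fe <- frobenius_error(M, candidate, k)
  structure(
    list(sse_ratio = ratio,
         ccc_singular_values = ccc_sv,
         ccc_pc = ccc_pc,
         absolute_error = fe$absolute,
         relative_error = fe$relative,
         relative_error_divisor = fe$divisor,
         k = as.integer(k)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  # presentation rounding matches the conventional table precision: 6
  # decimals for the SSE ratio, 4 for CCC; full precision kept in the object
  cat("<metrics_report> k=", x$k, "\n",
      "  SSE ratio:            ", formatC(x$sse_ratio, format = "f", digits = 6), "\n",
      "  CCC (singular values): ", formatC(x$ccc_singular_values, format = "f", digits = 4), "\n",
      sep = "")
  for (nm in names(x$ccc_pc)) {
    cat("  CCC (", nm, "):            ",
        formatC(x$ccc_pc[[nm]], format = "f", digits = 4), "\n", sep = "")
  }
  cat("  Frobenius error:      ", format(x$absolute_error, digits = 4),
      " (relative ", format(x$relative_error, digits = 4), ")\n", sep = "")
  invisible(x)
}
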
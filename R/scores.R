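# Principal-component scores: sample coordinates U * diag(S), plus the share
# of captured variance each component carries.

#' Principal-component scores from a decomposition
#'
#' Scores are `U[, 1:k] %*% diag(S[1:k])` — for an exact decomposition of a
#' centered matrix this equals `M %*% V`, the usual PCA coordinates. The
#' variance-explained fractions use only the `k` singular values the
#' decomposition computed (a truncated decomposition cannot see the tail of
#' the spectrum), so they are shares of *captured* variance, summing to 1
#' over the available components rather than over the full spectrum.
#'
#' @param svd An `svd_result`.
#' @param k Number of components to score; default all of `svd$k`.
#' @param sample_ids Optional sample identifiers (length `nrow(U)`).
#' @return A `score_matrix`: `scores` (samples x k, columns labelled
#'   `PC1..PCk`), `sample_ids`, `component_labels`, `variance_explained`.
#' @examples
#' m <- make_lowrank(30, 10, spectrum = c(6, 3, 1), noise_sd = 0, seed = 2)$matrix
#' sc <- pc_scores(exact_svd(m, k = 3))
#' sc$variance_explained
#' @export
pc_scores <- function(svd, k = NULL, sample_ids = NULL) {
  stopifnot(inherits(svd, "svd_result"))
  if (is.null(k)) k <- svd$k
  k <- as.integer(k)
  if (k < 1L) stop("invalid rank: k must be >= 1")
  if (k > svd$k) {
    stop("insufficient components: requested ", k, ", decomposition has ", svd$k)
  }
  idx <- seq_len(k)
  scores <- svd$U[, idx, drop = FALSE] %*% diag(svd$S[idx], nrow = k)
  labels <- paste0("PC", idx)
  colnames(scores) <- labels

  total <- sum(svd$S^2)
  if (total == 0) {
    warning("all singular values are zero; variance explained undefined")
    ve <- rep(0, k)
  } else {
    ve <- svd$S[idx]^2 / total
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(scores)))
  structure(
    list(scores = scores, sample_ids = sample_ids,
         component_labels = labels, variance_explained = ve),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", nrow(x$scores), " samples x ",
      ncol(x$scores), " components | captured-variance shares: ",
      paste(signif(utils::head(x$variance_explained, 4L), 4L), collapse = ", "),
      if (length(x$variance_explained) > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}
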
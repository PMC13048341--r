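# Synthetic fixtures with known ground truth: low-rank-plus-noise matrices
# whose singular spectrum is chosen exactly, and negative-binomial count
# matrices shaped like single-cell / spatial transcriptomics data (genes x
# cells, sparse, non-negative integers) at desk scale.

#' Low-rank matrix with a known singular spectrum
#'
#' Builds `U diag(spectrum) V' + noise_sd * G` where `U` (n x r) and `V`
#' (m x r) are orthonormal factors obtained by QR of seeded Gaussian
#' matrices, and `G` has i.i.d. standard normal entries. With
#' `noise_sd = 0` the matrix has exactly the requested spectrum and rank.
#' The truth factors carry the same sign convention as the decomposition
#' routines, so estimated and true factors are directly comparable.
#'
#' @param n,m Matrix dimensions (>= 2).
#' @param spectrum Positive non-increasing vector of true singular values,
#'   length at most `min(n, m)`.
#' @param noise_sd Standard deviation of the added Gaussian noise.
#' @param seed Integer seed; the same call is bit-reproducible.
#' @return A `synthetic_truth` list: `matrix`, `true_spectrum`, `true_U`,
#'   `true_V`, `noise_sd`, `seed`.
#' @examples
#' tr <- make_lowrank(6, 4, spectrum = c(4, 2), noise_sd = 0, seed = 1)
#' exact_svd(tr$matrix)$S[1:2]  # 4 2
#' @export
make_lowrank <- function(n, m, spectrum, noise_sd = 0, seed = 1L) {
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(n >= 2L, m >= 2L, is.numeric(spectrum), length(spectrum) >= 1L,
            all(spectrum > 0), is.numeric(noise_sd), noise_sd >= 0)
  if (is.unsorted(rev(spectrum))) stop("invalid spectrum: must be non-increasing")
  r <- length(spectrum)
  if (r > min(n, m)) stop("invalid spectrum: longer than min(n, m)")
  seed <- as.integer(seed)

  draws <- with_isolated_seed(seed, {
    list(gu = matrix(stats::rnorm(n * r), n, r),
         gv = matrix(stats::rnorm(m * r), m, r),
         noise = if (noise_sd > 0) matrix(stats::rnorm(n * m), n, m) else NULL)
  })
  U <- qr.Q(qr(draws$gu))
  V <- qr.Q(qr(draws$gv))
  fl <- apply_sign_convention(U, t(V))
  U <- fl$U
  V <- t(fl$Vt)
  M <- U %*% (spectrum * t(V))
  if (noise_sd > 0) M <- M + noise_sd * draws$noise
  structure(
    list(matrix = M, true_spectrum = spectrum, true_U = U, true_V = V,
         noise_sd = noise_sd, seed = seed),
    class = "synthetic_truth"
  )
}

#' Synthetic single-cell-like count matrix
#'
#' Emulates the structure of a spatial/single-cell expression matrix: a
#' sparse non-negative integer matrix of genes x cells (features by
#' samples), drawn from a negative binomial (Gamma-Poisson, the standard
#' model for sequencing counts) around a rank-`n_programs` non-negative
#' rate matrix. Rates are the softplus of a low-rank Gaussian factor
#' product, rescaled so the mean count equals `mean_depth`.
#'
#' @param n_cells,n_genes Output dimensions (cells are the samples).
#' @param n_programs Number of latent expression programs (the effective
#'   rank of the rate matrix), at most `min(n_cells, n_genes)`.
#' @param mean_depth Mean count per matrix entry.
#' @param dispersion Negative-binomial size parameter; variance is
#'   `mu + mu^2 / dispersion`, so large values approach Poisson.
#' @param seed Integer seed.
#' @return A `raw_matrix` (sparse, `features_by_samples`) with
#'   auto-generated `gene_####` / `cell_####` names.
#' @export
make_counts <- function(n_cells, n_genes, n_programs = 3L, mean_depth = 5,
                        dispersion = 2, seed = 1L) {
  n_cells <- as.integer(n_cells); n_genes <- as.integer(n_genes)
  n_programs <- as.integer(n_programs)
  if (n_cells < 2L || n_genes < 2L || n_programs < 1L ||
      n_programs > min(n_cells, n_genes) ||
      !is.numeric(mean_depth) || mean_depth <= 0 ||
      !is.numeric(dispersion) || dispersion <= 0) {
    stop("invalid generator parameter")
  }
  seed <- as.integer(seed)
  counts <- with_isolated_seed(seed, {
    L <- matrix(stats::rnorm(n_genes * n_programs), n_genes, n_programs)
    R <- matrix(stats::rnorm(n_programs * n_cells), n_programs, n_cells)
    eta <- (L %*% R) / sqrt(n_programs)
    rate <- log1p(exp(eta))               # softplus keeps rates positive
    rate <- rate * (mean_depth / mean(rate))
    matrix(stats::rnbinom(n_genes * n_cells, size = dispersion, mu = rate),
           n_genes, n_cells)
  })
  m <- Matrix::Matrix(counts, sparse = TRUE)
  new_raw_matrix(
    m,
    row_names = sprintf("gene_%04d", seq_len(n_genes)),
    col_names = sprintf("cell_%04d", seq_len(n_cells)),
    orientation = "features_by_samples"
  )
}
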
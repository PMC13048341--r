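# Matrix preparation: orient to samples x features, then log-transform,
# center and scale in that fixed order. The output is the dense matrix the
# decomposition core consumes, with full provenance of what was applied.

#' Prepare a raw matrix for decomposition
#'
#' Applies, in fixed order: transpose (so rows are samples and columns are
#' features), `log(x + pseudocount)`, column mean-centering, and column
#' scaling to unit sample standard deviation (n - 1 denominator). Sparse
#' input is densified. Each step is recorded in the result's `provenance`.
#'
#' Orientation: if the raw matrix declares `features_by_samples` it is
#' transposed; `samples_by_features` is kept as-is. With `orientation =
#' "auto"` on an undeclared matrix, the longer axis is taken to be the
#' samples (single-cell matrices have many more cells than genes); a square
#' undeclared matrix is refused as ambiguous.
#'
#' Zero-variance features only matter when `scale = TRUE` (scaling would
#' divide by zero); `zero_variance_policy` then chooses between dropping the
#' feature (default, with a warning naming it in the provenance), keeping it
#' as an all-zero column, or raising an error.
#'
#' @param raw A `raw_matrix` from [read_matrix()] or [make_counts()].
#' @param orientation `"auto"` (default) or an explicit override of the
#'   stored orientation.
#' @param log_base `NULL` for no log transform, `2`, or `exp(1)`.
#' @param pseudocount Value added before the log; must be positive when the
#'   matrix contains zeros and a log is requested. Default 1.
#' @param center Mean-center each feature column.
#' @param scale Scale each feature column to unit sample standard deviation.
#' @param zero_variance_policy `"drop"`, `"keep_zero"`, or `"error"`.
#' @return A `prepared_matrix`: dense `values` (samples x features),
#'   `sample_ids`, `feature_ids`, `provenance`, and the column means/sds used
#'   (when centering/scaling was applied).
#' @examples
#' raw <- make_counts(n_cells = 60, n_genes = 20, n_programs = 2,
#'                    mean_depth = 10, dispersion = 2, seed = 1)
#' prep <- prep_matrix(raw, log_base = 2, center = TRUE, scale = TRUE)
#' dim(prep$values)  # 60 x <= 20
#' @export
prep_matrix <- function(raw,
                        orientation = c("auto", "samples_by_features",
                                        "features_by_samples"),
                        log_base = NULL, pseudocount = 1,
                        center = FALSE, scale = FALSE,
                        zero_variance_policy = c("drop", "keep_zero", "error")) {
  stopifnot(inherits(raw, "raw_matrix"))
  orientation <- match.arg(orientation)
  zero_variance_policy <- match.arg(zero_variance_policy)
  if (!is.null(log_base)) {
    stopifnot(is.numeric(log_base), length(log_base) == 1L, log_base > 0)
  }
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount >= 0)

  eff_orient <- if (orientation == "auto") raw$orientation else orientation
  if (eff_orient == "unknown") {
    d <- dim(raw$values)
    if (d[[1L]] == d[[2L]]) {
      stop("orientation ambiguous: square matrix with no declared orientation")
    }
    # cells/spots outnumber genes/probes in the data this targets
    eff_orient <- if (d[[1L]] >= d[[2L]]) "samples_by_features" else "features_by_samples"
  }

  values <- as.matrix(raw$values)
  sample_ids <- raw$row_names
  feature_ids <- raw$col_names
  transposed <- eff_orient == "features_by_samples"
  if (transposed) {
    values <- t(values)
    sample_ids <- raw$col_names
    feature_ids <- raw$row_names
  }
  n <- nrow(values)
  if (n < 2L) stop("need at least 2 samples")
  if (ncol(values) < 1L) stop("need at least 1 feature")
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(ncol(values)))

  if (!is.null(log_base)) {
    if (any(values < 0)) stop("negative values under log")
    if (pseudocount == 0 && any(values == 0)) {
      stop("pseudocount must be > 0 when the matrix contains zeros")
    }
    values <- log(values + pseudocount, base = log_base)
  }

  col_means <- NULL
  if (center) {
    col_means <- colMeans(values)
    values <- sweep(values, 2L, col_means, "-")
  }

  col_sds <- NULL
  dropped <- character(0)
  if (scale) {
    col_sds <- apply(values, 2L, stats::sd)
    zero_var <- col_sds < 1e-12
    if (any(zero_var)) {
      if (zero_variance_policy == "error") {
        stop("zero variance feature: ",
             paste(feature_ids[zero_var], collapse = ", "))
      }
      if (zero_variance_policy == "drop") {
        dropped <- feature_ids[zero_var]
        warning("dropping ", sum(zero_var), " zero-variance feature(s): ",
                paste(utils::head(dropped, 5L), collapse = ", "),
                if (sum(zero_var) > 5L) ", ..." else "")
        values <- values[, !zero_var, drop = FALSE]
        feature_ids <- feature_ids[!zero_var]
        if (!is.null(col_means)) col_means <- col_means[!zero_var]
        col_sds <- col_sds[!zero_var]
        if (ncol(values) < 1L) stop("all features had zero variance")
      } else { # keep_zero: the column is retained but zeroed out
        col_sds[zero_var] <- 1
        values[, zero_var] <- 0
      }
    }
    values <- sweep(values, 2L, col_sds, "/")
  }

  structure(
    list(values = values,
         sample_ids = sample_ids,
         feature_ids = feature_ids,
         provenance = list(
           transposed = transposed,
           log_base = log_base,
           pseudocount = pseudocount,
           centered = center,
           scaled = scale,
           zero_variance_policy = zero_variance_policy,
           dropped_features = dropped),
         col_means = col_means,
         col_sds = col_sds),
    class = "prepared_matrix"
  )
}

#' @export
print.prepared_matrix <- function(x, ...) {
  p <- x$provenance
  cat("<prepared_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " features | transposed=", p$transposed,
      " log=", if (is.null(p$log_base)) "none" else format(p$log_base),
      " centered=", p$centered, " scaled=", p$scaled, "\n", sep = "")
  invisible(x)
}
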
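# On-disk interchange: decompositions as U.tsv / S.tsv / Vt.tsv + meta.json,
# scores and variance-explained as headed TSV, metrics as JSON + TSV. Floats
# are written with full round-trip precision (R's digits = 17 guarantees
# exact double recovery).

.write_num_tsv <- function(m, path, col.names = FALSE) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

#' Write an `svd_result` to a directory
#'
#' Produces `U.tsv`, `S.tsv`, `Vt.tsv` (tab-delimited, full precision) and
#' `meta.json` (method, k, seed, oversample, power_iters, backend), enough
#' to reload the decomposition with [read_svd_result()].
#'
#' @param svd An `svd_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_svd_result <- function(svd, dir) {
  stopifnot(inherits(svd, "svd_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_num_tsv(svd$U, file.path(dir, "U.tsv"))
  .write_num_tsv(matrix(svd$S, ncol = 1L), file.path(dir, "S.tsv"))
  .write_num_tsv(svd$Vt, file.path(dir, "Vt.tsv"))
  meta <- list(method = svd$method, k = svd$k, backend = svd$backend_name,
               seed = svd$seed, oversample = svd$oversample,
               power_iters = svd$power_iters)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1L))],
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an `svd_result` written by [write_svd_result()]
#' @param dir Directory containing `U.tsv`, `S.tsv`, `Vt.tsv`, `meta.json`.
#' @return An `svd_result`.
#' @export
read_svd_result <- function(dir) {
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f), sep = "\t"))
  U <- unname(rd("U.tsv"))
  S <- as.numeric(rd("S.tsv"))
  Vt <- unname(rd("Vt.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  new_svd_result(U, S, Vt, as.integer(meta$k), meta$method, meta$backend,
                 seed = meta$seed,
                 oversample = if (is.null(meta$oversample)) NULL else as.integer(meta$oversample),
                 power_iters = if (is.null(meta$power_iters)) NULL else as.integer(meta$power_iters))
}

#' Write a `score_matrix` to a directory
#'
#' `scores.tsv` has a leading `sample_id` column and one column per
#' component; `variance_explained.tsv` lists the captured-variance share of
#' each component.
#'
#' @param scores A `score_matrix` from [pc_scores()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_score_matrix <- function(scores, dir) {
  stopifnot(inherits(scores, "score_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(sample_id = scores$sample_ids,
                   format(scores$scores, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("sample_id", scores$component_labels)
  utils::write.table(df, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ve <- data.frame(component = scores$component_labels,
                   variance_explained = format(scores$variance_explained,
                                               digits = 17, trim = TRUE))
  utils::write.table(ve, file.path(dir, "variance_explained.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a `metrics_report` as JSON (full precision) and TSV (table precision)
#'
#' The TSV rounds to the conventional presentation precision (SSE ratio to
#' 6 decimals, CCC to 4, half-to-even); the JSON keeps full precision.
#'
#' @param report A `metrics_report` from [compare_decompositions()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_metrics_report <- function(report, dir) {
  stopifnot(inherits(report, "metrics_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rows <- data.frame(
    metric = c("sse_ratio", "ccc_singular_values",
               paste0("ccc_", tolower(names(report$ccc_pc))),
               "absolute_error", "relative_error"),
    value = c(sprintf("%.6f", round(report$sse_ratio, 6L)),
              sprintf("%.4f", round(report$ccc_singular_values, 4L)),
              sprintf("%.4f", round(report$ccc_pc, 4L)),
              format(report$absolute_error, digits = 6),
              format(report$relative_error, digits = 6))
  )
  utils::write.table(rows, file.path(dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
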
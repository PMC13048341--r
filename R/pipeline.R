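# End-to-end pipeline: read -> prep -> decompose -> score -> write. All
# configuration is validated up front (one aggregated error message), every
# default is materialized into the run's meta.json, and outputs are
# deterministic for a fixed configuration.

#' Default pipeline configuration
#'
#' Returns the fully materialized default `run_config`; any subset can be
#' overridden via [run_pipeline()]'s `...` or by passing a modified list.
#'
#' @return A named list of configuration fields.
#' @export
default_config <- function() {
  list(
    input = NULL,                 # path, or a raw_matrix object directly
    format = "mtx",               # mtx | delimited
    delimiter = ",",
    header = TRUE,
    orientation = "auto",         # auto | samples_by_features | features_by_samples
    log_base = 2,                 # NULL disables the log transform
    pseudocount = 1,
    center = TRUE,
    scale = TRUE,
    zero_variance_policy = "drop",
    method = "randomized",        # randomized | exact
    k = 50L,
    oversample = NULL,            # NULL: min(10, min(dim) - k)
    power_iters = 2L,
    seed = 1L,
    backend = "reference",
    threads = "auto",
    device = "cpu",
    output_dir = NULL
  )
}

.validate_config <- function(config) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(!is.null(config$input), "input: required (path or raw_matrix)")
  if (is.character(config$input)) {
    chk(file.exists(config$input), paste0("input: file not found: ", config$input))
    chk(config$format %in% c("mtx", "delimited"), "format: must be mtx or delimited")
  } else {
    chk(inherits(config$input, "raw_matrix"), "input: must be a path or raw_matrix")
  }
  chk(config$method %in% c("exact", "randomized"), "method: must be exact or randomized")
  chk(is.numeric(config$k) && length(config$k) == 1L && config$k >= 1,
      "k: must be a positive integer")
  chk(is.null(config$oversample) ||
        (is.numeric(config$oversample) && config$oversample >= 0),
      "oversample: must be >= 0")
  chk(is.numeric(config$power_iters) && config$power_iters >= 0, "power_iters: must be >= 0")
  chk(is.numeric(config$seed), "seed: must be an integer")
  chk(is.numeric(config$pseudocount) && config$pseudocount >= 0,
      "pseudocount: must be >= 0")
  chk(config$zero_variance_policy %in% c("drop", "keep_zero", "error"),
      "zero_variance_policy: must be drop, keep_zero or error")
  chk(config$orientation %in% c("auto", "samples_by_features", "features_by_samples"),
      "orientation: invalid")
  chk(config$device %in% c("cpu", "gpu"), "device: must be cpu or gpu")
  chk(is.character(config$output_dir) && length(config$output_dir) == 1L,
      "output_dir: required")
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(config)
}

#' Run the full preparation / decomposition / scoring pipeline
#'
#' Reads the input matrix, prepares it (orientation, log, center, scale),
#' decomposes it with the configured method, computes PC scores, and writes
#' `prep.json`, `U.tsv`/`S.tsv`/`Vt.tsv`/`meta.json`, `scores.tsv` and
#' `variance_explained.tsv` to the output directory. `meta.json` contains
#' every effective parameter, so a run is exactly reproducible from it. On
#' any stage failure the partially written directory is renamed with an
#' `.incomplete` suffix before the error propagates.
#'
#' @param config A configuration list (see [default_config()]); missing
#'   fields take their defaults.
#' @param ... Individual field overrides, e.g. `run_pipeline(config, k = 20)`.
#' @return Invisibly, a list with the `svd_result`, `score_matrix`,
#'   `prepared_matrix` and `output_dir`.
#' @examples
#' raw <- make_counts(n_cells = 80, n_genes = 30, seed = 7)
#' out <- run_pipeline(list(input = raw, k = 5,
#'                          output_dir = file.path(tempdir(), "demo")))
#' out$svd$S
#' @export
run_pipeline <- function(config = list(), ...) {
  config <- utils::modifyList(default_config(), utils::modifyList(config, list(...)))
  .validate_config(config)
  out_dir <- config$output_dir

  run <- function() {
    raw <- if (is.character(config$input)) {
      read_matrix(config$input, format = config$format,
                  delimiter = config$delimiter, header = config$header)
    } else {
      config$input
    }
    message("[pipeline] input: ", nrow(raw$values), " x ", ncol(raw$values),
            if (raw$sparse) " (sparse)" else "")
    prep <- prep_matrix(raw, orientation = config$orientation,
                        log_base = config$log_base,
                        pseudocount = config$pseudocount,
                        center = config$center, scale = config$scale,
                        zero_variance_policy = config$zero_variance_policy)
    message("[pipeline] prepared: ", nrow(prep$values), " samples x ",
            ncol(prep$values), " features")
    backend <- resolve_backend(config$backend, threads = config$threads,
                               device = config$device)
    svd <- if (config$method == "exact") {
      truncate_svd(exact_svd(prep, backend = backend), config$k)
    } else {
      randomized_svd(prep, k = config$k, oversample = config$oversample,
                     power_iters = config$power_iters, seed = config$seed,
                     backend = backend)
    }
    message("[pipeline] ", config$method, " SVD done, k = ", svd$k)
    scores <- pc_scores(svd, sample_ids = prep$sample_ids)

    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(prep$provenance, file.path(out_dir, "prep.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_svd_result(svd, out_dir)
    # meta.json gains the full effective configuration for reproducibility
    cfg <- config
    cfg$input <- if (is.character(config$input)) config$input else "<in-memory raw_matrix>"
    # materialize the effective sketch parameters the decomposition used
    if (!is.null(svd$oversample)) cfg$oversample <- svd$oversample
    if (!is.null(svd$power_iters)) cfg$power_iters <- svd$power_iters
    jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1L))],
                         file.path(out_dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_score_matrix(scores, out_dir)
    list(svd = svd, scores = scores, prepared = prep, output_dir = out_dir)
  }

  result <- tryCatch(run(), error = function(e) {
    if (dir.exists(out_dir)) {
      file.rename(out_dir, paste0(sub("/+$", "", out_dir), ".incomplete"))
    }
    stop(e)
  })
  invisible(result)
}
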
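# Matrix ingestion: Matrix Market coordinate files (sparse counts, with
# optional plain-text name sidecars) and delimited dense text. Both return a
# `raw_matrix`, the untransformed container that prep_matrix() consumes.

new_raw_matrix <- function(values, row_names = NULL, col_names = NULL,
                           orientation = c("unknown", "samples_by_features",
                                           "features_by_samples")) {
  orientation <- match.arg(orientation)
  if (!is.null(row_names) && length(row_names) != nrow(values)) {
    stop("dimension mismatch: ", length(row_names), " row names for ",
         nrow(values), " rows")
  }
  if (!is.null(col_names) && length(col_names) != ncol(values)) {
    stop("dimension mismatch: ", length(col_names), " column names for ",
         ncol(values), " columns")
  }
  vals <- if (inherits(values, "sparseMatrix")) values@x else values
  if (anyNA(vals)) stop("invalid value: matrix contains NaN/NA entries")
  structure(
    list(values = values,
         row_names = row_names,
         col_names = col_names,
         orientation = orientation,
         sparse = inherits(values, "sparseMatrix")),
    class = "raw_matrix"
  )
}

#' @export
print.raw_matrix <- function(x, ...) {
  cat("<raw_matrix> ", nrow(x$values), " x ", ncol(x$values),
      if (x$sparse) " (sparse)" else " (dense)",
      " | orientation: ", x$orientation, "\n", sep = "")
  invisible(x)
}

#' Read a matrix from Matrix Market or delimited text
#'
#' Matrix Market coordinate files are read with [Matrix::readMM()] after a
#' lightweight validation pass that reports the offending line on malformed
#' headers or truncated entry lists. Name sidecars `<stem>.rownames.txt` and
#' `<stem>.colnames.txt` (one name per line, `<stem>` = path without the
#' `.mtx` extension) are attached when present. Delimited files are parsed
#' with [utils::read.table()].
#'
#' @param path Path to the matrix file.
#' @param format `"mtx"` or `"delimited"`.
#' @param delimiter Field separator for delimited files (default `","`).
#' @param header Does the delimited file carry a header row of feature names?
#' @param row_names_col Column index holding row names in a delimited file,
#'   or `NULL` (default) for none.
#' @param orientation Declared orientation of the stored matrix; `"unknown"`
#'   defers the decision to [prep_matrix()]'s auto-detection.
#' @return A `raw_matrix`: the values (sparse storage preserved for mtx),
#'   optional row/column names, and the declared orientation.
#' @export
read_matrix <- function(path, format = c("mtx", "delimited"), delimiter = ",",
                        header = TRUE, row_names_col = NULL,
                        orientation = c("unknown", "samples_by_features",
                                        "features_by_samples")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    .read_mtx(path, orientation)
  } else {
    .read_delimited(path, delimiter, header, row_names_col, orientation)
  }
}

.read_mtx <- function(path, orientation) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[[1L]], "%%MatrixMarket")) {
    stop("parse error at line 1: missing %%MatrixMarket banner")
  }
  body_idx <- which(!startsWith(lines, "%"))
  if (length(body_idx) == 0L) stop("parse error: no size line after comments")
  size_line <- body_idx[[1L]]
  dims <- suppressWarnings(as.numeric(strsplit(trimws(lines[[size_line]]), "\\s+")[[1L]]))
  if (length(dims) != 3L || anyNA(dims)) {
    stop("parse error at line ", size_line, ": expected 'rows cols nnz'")
  }
  n_entries <- length(body_idx) - 1L
  if (n_entries != dims[[3L]]) {
    stop("parse error at line ", size_line, ": header declares ", dims[[3L]],
         " entries but ", n_entries, " found")
  }
  m <- Matrix::readMM(path)
  if (anyNA(m@x)) stop("invalid value: matrix contains NaN/NA entries")
  stem <- sub("\\.mtx$", "", path)
  rn <- .read_sidecar(paste0(stem, ".rownames.txt"), nrow(m), "row")
  cn <- .read_sidecar(paste0(stem, ".colnames.txt"), ncol(m), "column")
  new_raw_matrix(m, rn, cn, orientation)
}

.read_sidecar <- function(path, expected, axis) {
  if (!file.exists(path)) return(NULL)
  nm <- readLines(path, warn = FALSE)
  if (length(nm) != expected) {
    stop("dimension mismatch: ", length(nm), " ", axis, " names in ",
         basename(path), " for ", expected, " ", axis, "s")
  }
  nm
}

.read_delimited <- function(path, delimiter, header, row_names_col, orientation) {
  df <- utils::read.table(path, sep = delimiter, header = header,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  rn <- NULL
  if (!is.null(row_names_col)) {
    rn <- as.character(df[[row_names_col]])
    df <- df[, -row_names_col, drop = FALSE]
  }
  if (!all(vapply(df, is.numeric, logical(1L)))) {
    stop("parse error: non-numeric data column (is row_names_col set correctly?)")
  }
  values <- as.matrix(df)
  dimnames(values) <- NULL
  cn <- if (header) colnames(df) else NULL
  new_raw_matrix(values, rn, cn, orientation)
}

#' Write a raw matrix to disk
#'
#' Sparse matrices go to Matrix Market coordinate format (via
#' [Matrix::writeMM()]) with `.rownames.txt` / `.colnames.txt` sidecars;
#' dense matrices to tab-delimited text. The file can be read back with
#' [read_matrix()].
#'
#' @param raw A `raw_matrix`.
#' @param path Output path (`.mtx` for sparse, anything for dense TSV).
#' @return Invisibly, `path`.
#' @export
write_raw_matrix <- function(raw, path) {
  stopifnot(inherits(raw, "raw_matrix"))
  if (raw$sparse) {
    Matrix::writeMM(methods::as(raw$values, "CsparseMatrix"), path)
    stem <- sub("\\.mtx$", "", path)
    if (!is.null(raw$row_names)) {
      writeLines(raw$row_names, paste0(stem, ".rownames.txt"))
    }
    if (!is.null(raw$col_names)) {
      writeLines(raw$col_names, paste0(stem, ".colnames.txt"))
    }
  } else {
    df <- as.data.frame(raw$values)
    if (!is.null(raw$col_names)) names(df) <- raw$col_names
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !is.null(raw$col_names))
  }
  invisible(path)
}
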
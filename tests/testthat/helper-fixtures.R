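# Shared fixture builders. Everything is generated in code at test time;
# no fixture files ship with the package.

# deterministic dense test matrix, entries O(1)
seeded_matrix <- function(n, m, seed) {
  tr <- make_lowrank(n, m, spectrum = rev(seq_len(min(n, m))) + 0.5,
                     noise_sd = 0.3, seed = seed)
  tr$matrix
}

# write a small Matrix Market file (optionally with name sidecars) into a
# fresh temp dir; returns the .mtx path
write_tmp_mtx <- function(entries, nrow, ncol, row_names = NULL,
                          col_names = NULL, dir = withr_tempdir()) {
  path <- file.path(dir, "m.mtx")
  header <- c("%%MatrixMarket matrix coordinate real general",
              paste(nrow, ncol, nrow(entries)))
  body <- apply(entries, 1L, function(e) paste(e[1L], e[2L], e[3L]))
  writeLines(c(header, body), path)
  if (!is.null(row_names)) writeLines(row_names, file.path(dir, "m.rownames.txt"))
  if (!is.null(col_names)) writeLines(col_names, file.path(dir, "m.colnames.txt"))
  path
}

withr_tempdir <- function() {
  d <- tempfile("fixture")
  dir.create(d)
  d
}

# independent oracle for singular values: sqrt of eigenvalues of M'M
# (normal equations), never touching svd()
normal_equations_singular_values <- function(M) {
  ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

max_rel_diff <- function(a, b) max(abs(a - b) / pmax(abs(b), .Machine$double.eps))
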
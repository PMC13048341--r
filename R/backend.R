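# Registry of numeric backends. A backend bundles the four dense-linear-algebra
# primitives the decomposition core needs (matmul, thin QR with orthonormal Q,
# full SVD of a small dense matrix, seeded Gaussian sampling) so that the SVD
# routines never call BLAS-wrapping functions directly. The "reference" backend
# is pure base R and always present; accelerated backends can be registered at
# runtime with the same contract.
.backend_registry <- new.env(parent = emptyenv())

#' Register a numeric backend
#'
#' A backend factory is a function `function(threads, device)` returning a
#' list with elements `matmul(a, b)`, `qr(m)` (returning `list(Q, R)` with
#' orthonormal thin `Q`), `svd_small(m)` (returning `list(u, d, vt)` with
#' singular values in decreasing order), `gaussian(n, m, seed)` (an `n x m`
#' matrix of i.i.d. standard normals, reproducible from `seed`), plus
#' `threads` (effective thread count actually in use, an integer >= 1),
#' `device` (`"cpu"` or `"gpu"`), and `gpu_available` (logical).
#'
#' @param name Backend identifier.
#' @param factory Factory function as described above.
#' @return Invisibly, `name`.
#' @export
register_backend <- function(name, factory) {
  stopifnot(is.character(name), length(name) == 1L, is.function(factory))
  assign(name, factory, envir = .backend_registry)
  invisible(name)
}

#' List registered backends
#' @return Character vector of backend names.
#' @export
list_backends <- function() {
  sort(ls(.backend_registry))
}

#' Resolve a backend specification into a usable handle
#'
#' Validates the requested thread count and device against what the named
#' backend can provide. A GPU request on a backend without GPU support is an
#' error: there is no silent fallback to CPU, so a benchmark configured for
#' one device never quietly runs on another.
#'
#' @param name Backend name; `"reference"` (base R, always available) by
#'   default.
#' @param threads Positive integer or `"auto"`. The reference backend performs
#'   its linear algebra through base R (single R-level thread) and reports the
#'   thread count it actually uses.
#' @param device `"cpu"` or `"gpu"`.
#' @return A `svd_backend` handle exposing the primitives described in
#'   [register_backend()].
#' @examples
#' b <- resolve_backend("reference")
#' qr3 <- b$qr(diag(3))
#' @export
resolve_backend <- function(name = "reference", threads = "auto", device = c("cpu", "gpu")) {
  device <- match.arg(device)
  if (!is.character(name) || length(name) != 1L) {
    stop("backend name must be a single string")
  }
  if (!exists(name, envir = .backend_registry, inherits = FALSE)) {
    stop("backend not found: '", name, "' (registered: ",
         paste(list_backends(), collapse = ", "), ")")
  }
  if (identical(threads, "auto")) {
    threads_req <- NA_integer_
  } else {
    threads_req <- suppressWarnings(as.integer(threads))
    if (is.na(threads_req) || threads_req < 1L) {
      stop("threads must be a positive integer or \"auto\"")
    }
  }
  factory <- get(name, envir = .backend_registry)
  handle <- factory(threads = threads_req, device = device)
  if (device == "gpu" && !isTRUE(handle$gpu_available)) {
    stop("device unavailable: backend '", name, "' has no GPU support")
  }
  handle$name <- name
  if (!is.integer(handle$threads) || handle$threads < 1L) {
    stop("backend '", name, "' reported an invalid effective thread count")
  }
  class(handle) <- "svd_backend"
  handle
}

#' @export
print.svd_backend <- function(x, ...) {
  cat("<svd_backend> ", x$name, " | threads=", x$threads,
      " | device=", x$device, "\n", sep = "")
  invisible(x)
}

# Run expr with the global RNG set from `seed`, restoring the caller's RNG
# state afterwards so sampling never perturbs user code or other draws.
with_isolated_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

.reference_backend_factory <- function(threads, device) {
  list(
    matmul = function(a, b) a %*% b,
    qr = function(m) {
      d <- qr(m)
      Q <- qr.Q(d)
      R <- qr.R(d)
      # normalize to a non-negative diagonal of R, making the thin QR of a
      # full-rank matrix unique (and qr(I) = (I, I))
      s <- sign(diag(R))
      s[s == 0] <- 1
      list(Q = sweep(Q, 2L, s, "*"), R = sweep(R, 1L, s, "*"))
    },
    svd_small = function(m) {
      d <- svd(m)
      list(u = d$u, d = d$d, vt = t(d$v))
    },
    gaussian = function(n, m, seed) {
      with_isolated_seed(seed, matrix(stats::rnorm(n * m), nrow = n, ncol = m))
    },
    # base R linear algebra runs on whatever BLAS the interpreter was built
    # with; from this package's side there is one thread of control
    threads = 1L,
    device = "cpu",
    gpu_available = FALSE
  )
}

.onLoad <- function(libname, pkgname) {
  register_backend("reference", .reference_backend_factory)
}
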
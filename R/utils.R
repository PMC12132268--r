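# Internal helpers shared across modules.

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}

as_dgc <- function(x) {
  if (inherits(x, "dgCMatrix")) return(x)
  methods::as(methods::as(x, "generalMatrix"), "CsparseMatrix")
}

# Fast matvec for a *symmetric* dgCMatrix: K u = (u' K)', and each column of
# the CSC structure is a contiguous segment, so the product reduces to
# segment sums of x * u[row]. Avoids S4 result-object construction.
sym_spmv <- function(K, u) {
  cs <- c(0, cumsum(K@x * u[K@i + 1L]))
  p <- K@p
  n <- length(p) - 1L
  cs[p[-1L] + 1L] - cs[p[-(n + 1L)] + 1L]
}

# Mass-matrix action with a fast path for the (default) lumped diagonal
# (pass the stored diagonal as md).
mass_mult <- function(Mm, v, md = NULL) {
  if (!is.null(md)) md * v else as.numeric(Mm %*% v)
}
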
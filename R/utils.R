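# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
# All package randomness goes through this; no function touches global seed state.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

as_num_matrix <- function(x, arg = deparse(substitute(x))) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  storage.mode(x) <- "double"
  x
}

# Maximum relative asymmetry, scaled by the largest entry magnitude.
asymmetry <- function(a) {
  m <- max(abs(a))
  if (m == 0) return(0)
  max(abs(a - t(a))) / m
}

# Random orthonormal matrix columns (dim x k) from the current RNG stream.
random_orthonormal <- function(dim, k = dim) {
  qr_z <- qr(matrix(stats::rnorm(dim * dim), dim, dim))
  q <- qr.Q(qr_z)
  # fix the QR sign ambiguity so results are stable across BLAS builds
  s <- sign(diag(qr.R(qr_z)))
  s[s == 0] <- 1
  q <- sweep(q, 2, s, `*`)
  q[, seq_len(k), drop = FALSE]
}

# Symmetric square root via eigendecomposition; tolerates PSD inputs.
sym_sqrt <- function(sigma) {
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}
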
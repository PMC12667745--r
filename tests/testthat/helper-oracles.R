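# Independent oracles and small utilities shared across tests.

# Brute-force generalized eigendecomposition via the dense nonsymmetric
# eigenproblem of solve(B) %*% A -- a different route than the package's
# Cholesky-whitening solver.
oracle_geigen <- function(sigma_t, sigma_b, mu = 0) {
  b <- sigma_b + diag(mu, nrow(sigma_b))
  e <- eigen(solve(b) %*% sigma_t)
  stopifnot(max(abs(Im(e$values))) < 1e-8)
  vals <- Re(e$values)
  ord <- order(vals, decreasing = TRUE)
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  # normalize to the background inner product for comparability
  for (j in seq_len(ncol(vecs))) {
    nrm <- sqrt(drop(crossprod(vecs[, j], b %*% vecs[, j])))
    vecs[, j] <- vecs[, j] / nrm
  }
  list(values = vals[ord], vectors = vecs)
}

# |cosine| between two directions.
abs_cos <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Largest principal angle (radians, small-angle regime) between the column
# spans of two bases, measured through its sine: the norm of the component of
# one orthonormal basis outside the span of the other. The sine form resolves
# angles down to machine precision, which acos of a cosine cannot.
subspace_angle <- function(u, v) {
  qu <- qr.Q(qr(u)); qv <- qr.Q(qr(v))
  r <- qv - qu %*% crossprod(qu, qv)
  s <- max(svd(r)$d)
  asin(min(1, s))
}

quad <- function(v, m) drop(crossprod(v, m %*% v))
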
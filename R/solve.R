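#' Maximize the Rayleigh quotient: the generalized eigenproblem
#'
#' Computes the top `d` solutions of \eqn{\hat\Sigma_T v = \lambda (\hat\Sigma_B + \mu I) v},
#' the symmetric-definite generalized eigenproblem whose leading eigenvector
#' maximizes the Rayleigh quotient
#' \eqn{\rho(v) = (v^\top \hat\Sigma_T v)/(v^\top \hat\Sigma_B v)} over all
#' nonzero directions. Each eigenvalue \eqn{\lambda_i} is the ratio of target
#' to background variance along its eigenvector, and the eigenvectors are
#' mutually orthonormal in the background inner product,
#' \eqn{v_i^\top (\hat\Sigma_B + \mu I) v_j = \delta_{ij}}.
#'
#' The solver whitens with a Cholesky factor of the (regularized) background:
#' with \eqn{\tilde B = R^\top R}, the problem reduces to an ordinary symmetric
#' eigendecomposition of \eqn{R^{-\top} \hat\Sigma_T R^{-1}}, and eigenvectors
#' are mapped back as \eqn{v = R^{-1} u}, which yields the background
#' normalization exactly.
#'
#' Regularization: with `mu = "auto"`, no shrinkage is applied when the
#' background is numerically positive definite (smallest eigenvalue above
#' `1e-10` times the largest); otherwise \eqn{\mu = 10^{-6}\,\mathrm{tr}(\hat\Sigma_B)/D},
#' a scale-aware additive Tikhonov shift. The `mu` actually applied is
#' recorded in the solution.
#'
#' Conventions: eigenvalues are returned in non-increasing order; each
#' eigenvector is sign-flipped so its largest-magnitude entry is positive
#' (first such entry on ties), making loadings tables reproducible. For
#' repeated eigenvalues only the spanned subspace is determined.
#'
#' @param pair A [cov_pair].
#' @param d Number of components to retain (1..D). Default: all D.
#' @param mu Nonnegative Tikhonov shrinkage applied to the background, or
#'   `"auto"` (see Details).
#' @return An object of class `rq_solution`: list with `vectors` (D x d,
#'   rownames = features, colnames `GE1..GEd`), `values` (length d,
#'   non-increasing), `mu` (shrinkage applied), `d`, `dim`, `feature_names`.
#' @examples
#' p <- cov_pair(diag(c(8, 2)), diag(c(2, 1)))
#' s <- solve_rho_pca(p)
#' s$values         # 4, 2
#' @export
solve_rho_pca <- function(pair, d = NULL, mu = "auto") {
  stopifnot(inherits(pair, "cov_pair"))
  D <- pair$dim
  d <- d %||% D
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d > D || d != round(d))
    stop(sprintf("`d` must be an integer in 1..%d", D), call. = FALSE)
  d <- as.integer(d)

  auto <- identical(mu, "auto")
  if (auto) {
    ev_b <- eigen(pair$sigma_b, symmetric = TRUE, only.values = TRUE)$values
    mu <- if (min(ev_b) > 1e-10 * max(ev_b, 0)) 0 else 1e-6 * sum(diag(pair$sigma_b)) / D
  } else if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0) {
    stop('`mu` must be a single nonnegative number or "auto"', call. = FALSE)
  }

  b_reg <- if (mu > 0) tikhonov_regularize(pair$sigma_b, mu) else pair$sigma_b
  ch <- tryCatch(chol(b_reg), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf(
      "background covariance plus mu*I (mu = %.3g) is not positive definite; increase `mu` or use mu = \"auto\"",
      mu), call. = FALSE)

  # whiten: M = R^{-T} A R^{-1}, symmetric; eigen of M, then map back v = R^{-1} u
  y <- forwardsolve(t(ch), pair$sigma_t)     # R^{-T} A
  m <- t(forwardsolve(t(ch), t(y)))          # R^{-T} A R^{-1}
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)

  vals <- e$values[seq_len(d)]
  vecs <- backsolve(ch, e$vectors[, seq_len(d), drop = FALSE])
  vecs <- fix_signs(vecs)
  dimnames(vecs) <- list(pair$feature_names, paste0("GE", seq_len(d)))
  names(vals) <- colnames(vecs)

  structure(
    list(vectors = vecs, values = vals, mu = mu, auto_mu = auto, d = d,
         dim = D, feature_names = pair$feature_names),
    class = "rq_solution")
}

# Flip each column so its largest-magnitude entry is positive (ties: first).
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' @export
print.rq_solution <- function(x, ...) {
  cat(sprintf("Generalized eigensolution: %d of %d components (mu = %.3g%s)\n",
              x$d, x$dim, x$mu, if (isTRUE(x$auto_mu)) ", auto" else ""))
  cat("Eigenvalues (target/background variance ratios):\n")
  print(signif(x$values, 5))
  invisible(x)
}

#' Write / read a generalized eigensolution as CSV
#'
#' `write_solution()` serializes a solution as two CSV files in `dir`:
#' `vectors.csv` (D x d loadings with a feature-name index column) and
#' `values.csv` (one row per component: `lambda`, `mu`, `d`).
#' `read_solution()` restores it.
#'
#' @param sol An `rq_solution`.
#' @param dir Directory (created if needed).
#' @return `write_solution()` returns `dir` invisibly; `read_solution()`
#'   returns an `rq_solution`.
#' @export
write_solution <- function(sol, dir) {
  stopifnot(inherits(sol, "rq_solution"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vec <- data.frame(feature = rownames(sol$vectors), sol$vectors,
                    check.names = FALSE)
  utils::write.csv(vec, file.path(dir, "vectors.csv"), row.names = FALSE)
  val <- data.frame(component = names(sol$values), lambda = unname(sol$values),
                    mu = sol$mu, d = sol$d)
  utils::write.csv(val, file.path(dir, "values.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_solution
#' @export
read_solution <- function(dir) {
  vec <- utils::read.csv(file.path(dir, "vectors.csv"), check.names = FALSE)
  val <- utils::read.csv(file.path(dir, "values.csv"))
  v <- as.matrix(vec[, -1, drop = FALSE])
  rownames(v) <- vec$feature
  values <- stats::setNames(val$lambda, val$component)
  structure(
    list(vectors = v, values = values, mu = val$mu[1], auto_mu = NA,
         d = val$d[1], dim = nrow(v), feature_names = vec$feature),
    class = "rq_solution")
}
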
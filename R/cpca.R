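#' Contrastive matrix for cPCA
#'
#' Forms \eqn{C_\alpha = \hat\Sigma_T - \alpha \hat\Sigma_B}, the matrix whose
#' eigendecomposition defines contrastive PCA. Although each term is a
#' covariance matrix, their difference need not be positive semidefinite:
#' \eqn{C_\alpha} can have negative eigenvalues, and no PSD check is applied.
#'
#' @param pair A [cov_pair].
#' @param alpha Nonnegative contrast strength.
#' @return Object of class `contrastive_matrix`: list with `c_alpha` (D x D
#'   symmetric matrix) and `alpha`.
#' @export
contrastive_matrix <- function(pair, alpha) {
  stopifnot(inherits(pair, "cov_pair"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("`alpha` must be a single nonnegative number", call. = FALSE)
  structure(list(c_alpha = pair$sigma_t - alpha * pair$sigma_b, alpha = alpha),
            class = "contrastive_matrix")
}

#' Top eigenpairs of a contrastive matrix
#'
#' The cPCA components: the top `d` eigenvectors of \eqn{C_\alpha} ordered by
#' algebraic eigenvalue (descending), Euclidean-orthonormal, with the same
#' sign convention as [solve_rho_pca()] (largest-magnitude entry positive).
#' At `alpha = 0` this is ordinary PCA of the target covariance.
#'
#' @param cm A [contrastive_matrix] (or a symmetric matrix).
#' @param d Number of components (default all).
#' @return List with `vectors` (D x d) and `values` (length d, may contain
#'   negative entries).
#' @export
cpca_components <- function(cm, d = NULL) {
  m <- if (inherits(cm, "contrastive_matrix")) cm$c_alpha else as_num_matrix(cm, "cm")
  if (nrow(m) != ncol(m) || asymmetry(m) > 1e-10)
    stop("contrastive matrix must be symmetric", call. = FALSE)
  m <- (m + t(m)) / 2
  D <- nrow(m)
  d <- d %||% D
  if (d < 1 || d > D || d != round(d))
    stop(sprintf("`d` must be an integer in 1..%d", D), call. = FALSE)
  e <- eigen(m, symmetric = TRUE)
  vecs <- fix_signs(e$vectors[, seq_len(d), drop = FALSE])
  dimnames(vecs) <- list(rownames(m), paste0("CPC", seq_len(d)))
  list(vectors = vecs, values = stats::setNames(e$values[seq_len(d)], colnames(vecs)))
}

#' First-order (Taylor) approximation of the Rayleigh quotient objective
#'
#' Evaluates the linearized objective obtained by expanding \eqn{1/x} about
#' \eqn{x_0 = 1/\beta}, where \eqn{x = v^\top \hat\Sigma_B v}: dropping
#' constants and an overall factor \eqn{2\beta},
#' \deqn{v^\top \hat\Sigma_T v \, (1 - (\beta/2)\, v^\top \hat\Sigma_B v).}
#' Up to the factor \eqn{2\beta} this is the cPCA objective
#' \eqn{v^\top \hat\Sigma_T v - \alpha\, v^\top \hat\Sigma_B v} with
#' \eqn{\alpha} proportional to \eqn{v^\top \hat\Sigma_T v}: cPCA is a
#' first-order approximation of the Rayleigh quotient, exact at the expansion
#' point and with error growing quadratically in \eqn{x - x_0}.
#'
#' @param v Nonzero vector of length D.
#' @param pair A [cov_pair].
#' @param beta Positive expansion parameter; the expansion point is
#'   \eqn{x_0 = 1/\beta}.
#' @return Scalar value of the approximate objective.
#' @export
cpca_taylor_objective <- function(v, pair, beta) {
  stopifnot(inherits(pair, "cov_pair"))
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  v <- as.numeric(v)
  if (all(v == 0)) stop("`v` must be a nonzero vector", call. = FALSE)
  qt <- drop(crossprod(v, pair$sigma_t %*% v))
  qb <- drop(crossprod(v, pair$sigma_b %*% v))
  qt * (1 - (beta / 2) * qb)
}

#' Default contrast-strength grid for cPCA comparisons
#'
#' `{0}` followed by `n` log-spaced values between `from` and `to`. Used when
#' scanning cPCA over its tuning parameter to compare against the
#' parameter-free Rayleigh-quotient solution.
#'
#' @param n Number of log-spaced positive values.
#' @param from,to Range of the positive part of the grid.
#' @return Numeric vector of length `n + 1` starting at 0.
#' @export
cpca_alpha_grid <- function(n = 40, from = 1e-2, to = 1e3) {
  c(0, exp(seq(log(from), log(to), length.out = n)))
}

#' Fit contrastive PCA (baseline)
#'
#' Eigendecomposition of \eqn{C_\alpha = \hat\Sigma_T - \alpha\hat\Sigma_B}
#' from two data matrices (samples x features) or a precomputed [cov_pair].
#' Provided as a faithful baseline for comparison with [rqpca()]; unlike the
#' Rayleigh-quotient solution it depends on the tuning parameter `alpha`.
#'
#' `pre_reduce` reproduces a behaviour of the original cPCA implementation
#' that first projects data with more than `pre_dim` features onto their top
#' `pre_dim` pooled principal components before contrasting. It degrades the
#' solution and is off by default.
#'
#' @param target,background Data matrices (samples x features, shared
#'   features), or `target` may be a [cov_pair] with `background` missing.
#' @param d Number of components.
#' @param alpha Contrast strength (single nonnegative value).
#' @param scale. Standard-scale each matrix separately before covariance
#'   (ignored for a `cov_pair` input).
#' @param pre_reduce Apply the pooled-PCA pre-reduction (see Details).
#' @param pre_dim Dimension of the pre-reduction.
#' @return Object of class `cpca`: `vectors`, `values`, `alpha`, `scores_t`,
#'   `scores_b` (when data matrices were supplied), `pair`.
#' @export
cpca <- function(target, background = NULL, d = 2, alpha = 1, scale. = TRUE,
                 pre_reduce = FALSE, pre_dim = 1000) {
  if (inherits(target, "cov_pair")) {
    pair <- target
    xt <- xb <- NULL
  } else {
    xt <- as_num_matrix(target, "target")
    xb <- as_num_matrix(background, "background")
    align_features(xt, xb)
    if (scale.) {
      xt <- standard_scale(xt)
      xb <- standard_scale(xb)
    }
    pair <- cov_pair(sample_covariance(xt), sample_covariance(xb),
                     feature_names = colnames(xt),
                     n_t = nrow(xt), n_b = nrow(xb))
  }
  basis <- NULL
  if (pre_reduce && pair$dim > pre_dim) {
    pooled <- (pair$sigma_t + pair$sigma_b) / 2
    basis <- eigen(pooled, symmetric = TRUE)$vectors[, seq_len(pre_dim), drop = FALSE]
    pair <- cov_pair(crossprod(basis, pair$sigma_t %*% basis),
                     crossprod(basis, pair$sigma_b %*% basis))
  }
  comp <- cpca_components(contrastive_matrix(pair, alpha), d)
  vectors <- comp$vectors
  if (!is.null(basis)) {
    vectors <- basis %*% vectors
    rownames(vectors) <- pair$feature_names
  }
  out <- list(vectors = vectors, values = comp$values, alpha = alpha,
              d = d, pair = pair, pre_reduce = pre_reduce)
  if (!is.null(xt)) {
    out$scores_t <- xt %*% vectors
    out$scores_b <- xb %*% vectors
  }
  structure(out, class = "cpca")
}

#' @export
print.cpca <- function(x, ...) {
  cat(sprintf("Contrastive PCA fit: %d components, alpha = %.4g\n", x$d, x$alpha))
  cat("Eigenvalues of the contrastive matrix:\n")
  print(signif(x$values, 5))
  if (any(x$values < 0))
    cat("(negative eigenvalues: the contrastive matrix is indefinite)\n")
  invisible(x)
}
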
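#' Target/background covariance pair
#'
#' Bundle a target covariance \eqn{\hat\Sigma_T} and a background covariance
#' \eqn{\hat\Sigma_B} over the same features into a validated container. All
#' Rayleigh-quotient machinery in this package operates on a `cov_pair`.
#'
#' Both matrices must be square of the same dimension and symmetric up to a
#' relative tolerance (they are symmetrized as \eqn{(A + A^\top)/2} to absorb
#' I/O round-off); the background must be positive semidefinite. Symmetry
#' violations beyond `symmetry_tol` are an error, never silently repaired.
#'
#' @param sigma_t Target covariance matrix (D x D).
#' @param sigma_b Background covariance matrix (D x D), positive semidefinite.
#' @param feature_names Optional character vector of D feature names; taken
#'   from `dimnames` when absent, else `f1..fD`.
#' @param n_t,n_b Optional sample counts (each at least 2) used to form the
#'   covariances; recorded for reporting only.
#' @param symmetry_tol Maximum allowed relative asymmetry `max|A - t(A)| / max|A|`.
#' @return An object of class `cov_pair`: a list with elements `sigma_t`,
#'   `sigma_b`, `feature_names`, `dim`, `n_t`, `n_b`.
#' @examples
#' p <- cov_pair(diag(c(4, 1)), diag(2))
#' rayleigh_quotient(c(1, 0), p)
#' @export
cov_pair <- function(sigma_t, sigma_b, feature_names = NULL,
                     n_t = NULL, n_b = NULL, symmetry_tol = 1e-10) {
  sigma_t <- as_num_matrix(sigma_t, "sigma_t")
  sigma_b <- as_num_matrix(sigma_b, "sigma_b")
  if (nrow(sigma_t) != ncol(sigma_t) || nrow(sigma_b) != ncol(sigma_b))
    stop("covariance matrices must be square", call. = FALSE)
  if (nrow(sigma_t) != nrow(sigma_b))
    stop(sprintf("dimension mismatch: target is %d x %d, background is %d x %d",
                 nrow(sigma_t), ncol(sigma_t), nrow(sigma_b), ncol(sigma_b)),
         call. = FALSE)
  d <- nrow(sigma_t)
  for (nm in c("sigma_t", "sigma_b")) {
    a <- if (nm == "sigma_t") sigma_t else sigma_b
    if (asymmetry(a) > symmetry_tol)
      stop(sprintf("`%s` is not symmetric (relative asymmetry %.3g exceeds %.3g)",
                   nm, asymmetry(a), symmetry_tol), call. = FALSE)
  }
  sigma_t <- (sigma_t + t(sigma_t)) / 2
  sigma_b <- (sigma_b + t(sigma_b)) / 2

  ev_b <- eigen(sigma_b, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_b) < -1e-8 * max(abs(ev_b), 1e-300))
    stop(sprintf(
      "background covariance is not positive semidefinite (min eigenvalue %.3g)",
      min(ev_b)), call. = FALSE)

  feature_names <- feature_names %||% rownames(sigma_t) %||% colnames(sigma_t) %||%
    paste0("f", seq_len(d))
  if (length(feature_names) != d)
    stop("`feature_names` must have one entry per feature", call. = FALSE)
  dimnames(sigma_t) <- dimnames(sigma_b) <- list(feature_names, feature_names)

  for (n in list(n_t = n_t, n_b = n_b)) {
    if (!is.null(n) && (length(n) != 1L || n < 2))
      stop("sample counts must be single values >= 2 when given", call. = FALSE)
  }
  structure(
    list(sigma_t = sigma_t, sigma_b = sigma_b, feature_names = feature_names,
         dim = d, n_t = n_t, n_b = n_b),
    class = "cov_pair")
}

#' @export
print.cov_pair <- function(x, ...) {
  cat(sprintf("Covariance pair: %d features\n", x$dim))
  if (!is.null(x$n_t) || !is.null(x$n_b))
    cat(sprintf("  samples: target n = %s, background n = %s\n",
                x$n_t %||% "?", x$n_b %||% "?"))
  cat(sprintf("  trace(target) = %.4g, trace(background) = %.4g\n",
              sum(diag(x$sigma_t)), sum(diag(x$sigma_b))))
  invisible(x)
}

#' Rayleigh quotient of a direction
#'
#' Evaluate \eqn{\rho(v) = (v^\top \hat\Sigma_T v) / (v^\top \hat\Sigma_B v)},
#' the ratio of target to background variance along `v`. The quotient is
#' invariant to rescaling of `v`. A direction in the null space of the
#' background covariance is an error (the background quadratic form must be
#' strictly positive), surfacing the need for regularization rather than
#' returning an infinite ratio.
#'
#' @param v Numeric vector of length D, nonzero.
#' @param pair A [cov_pair].
#' @return The scalar quotient.
#' @export
rayleigh_quotient <- function(v, pair) {
  stopifnot(inherits(pair, "cov_pair"))
  v <- as.numeric(v)
  if (length(v) != pair$dim)
    stop(sprintf("`v` has length %d but the pair has %d features",
                 length(v), pair$dim), call. = FALSE)
  if (all(v == 0)) stop("`v` must be a nonzero vector", call. = FALSE)
  den <- drop(crossprod(v, pair$sigma_b %*% v))
  if (den <= 0)
    stop(sprintf(
      "degenerate background: quadratic form t(v) %%*%% sigma_b %%*%% v = %.3g is not positive; consider Tikhonov regularization (mu > 0)",
      den), call. = FALSE)
  drop(crossprod(v, pair$sigma_t %*% v)) / den
}

#' Tikhonov regularization of a covariance matrix
#'
#' Additive shrinkage \eqn{\Sigma + \mu I}: every eigenvalue is shifted up by
#' exactly `mu` while eigenvectors are unchanged, so small eigenvalues are
#' lifted relatively strongly and large ones barely perturbed. Used to make a
#' rank-deficient background covariance invertible.
#'
#' @param sigma_b Symmetric matrix.
#' @param mu Nonnegative shrinkage strength.
#' @return `sigma_b + mu * I`.
#' @export
tikhonov_regularize <- function(sigma_b, mu) {
  sigma_b <- as_num_matrix(sigma_b, "sigma_b")
  if (nrow(sigma_b) != ncol(sigma_b) || asymmetry(sigma_b) > 1e-10)
    stop("`sigma_b` must be a symmetric square matrix", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    stop("`mu` must be a single nonnegative number", call. = FALSE)
  sigma_b + diag(mu, nrow(sigma_b))
}

#' Average replicate covariances into a single pair
#'
#' Given replicate target covariances \eqn{\hat\Sigma_{T_i}} and replicate
#' background covariances \eqn{\hat\Sigma_{B_j}}, form the (optionally
#' weighted) mean covariance on each side. Each replicate is an independent
#' estimate of the same population covariance, so averaging increases the
#' effective sample size; the Rayleigh quotient is then applied to the mean
#' covariances.
#'
#' @param target_covs List of symmetric D x D matrices (length >= 1).
#' @param background_covs List of symmetric D x D matrices (length >= 1).
#' @param weights_t,weights_b Optional nonnegative weights, one per replicate;
#'   normalized to sum to 1. Equal weights when omitted.
#' @param ... Passed to [cov_pair()] (e.g. `feature_names`).
#' @return A [cov_pair] of the averaged covariances.
#' @export
average_covariances <- function(target_covs, background_covs,
                                weights_t = NULL, weights_b = NULL, ...) {
  avg <- function(covs, w, side) {
    if (!is.list(covs) || length(covs) == 0)
      stop(sprintf("`%s` must be a non-empty list of matrices", side), call. = FALSE)
    covs <- lapply(covs, as_num_matrix, arg = side)
    d <- nrow(covs[[1]])
    for (m in covs)
      if (nrow(m) != d || ncol(m) != d)
        stop(sprintf("all %s replicates must share dimension %d x %d", side, d, d),
             call. = FALSE)
    if (is.null(w)) w <- rep(1 / length(covs), length(covs))
    if (length(w) != length(covs))
      stop(sprintf("`weights` must have one entry per %s replicate", side),
           call. = FALSE)
    if (any(w < 0)) stop("replicate weights must be nonnegative", call. = FALSE)
    if (sum(w) <= 0) stop("replicate weights must not all be zero", call. = FALSE)
    w <- w / sum(w)
    out <- matrix(0, d, d)
    for (i in seq_along(covs)) out <- out + w[i] * covs[[i]]
    (out + t(out)) / 2
  }
  cov_pair(avg(target_covs, weights_t, "target_covs"),
           avg(background_covs, weights_b, "background_covs"), ...)
}

#' Loewner (semidefinite) dominance test
#'
#' Returns `TRUE` when `a - b` is positive semidefinite up to numerical
#' tolerance, i.e. \eqn{A \succeq B} in the Loewner order. This is the order
#' under which the Rayleigh quotient is monotone: enlarging the target
#' covariance (or shrinking the background) in the Loewner order never
#' decreases the quotient at any direction.
#'
#' @param a,b Symmetric matrices of the same dimension.
#' @return Logical scalar.
#' @export
loewner_dominates <- function(a, b) {
  a <- as_num_matrix(a, "a"); b <- as_num_matrix(b, "b")
  if (!all(dim(a) == dim(b)) || nrow(a) != ncol(a))
    stop("`a` and `b` must be square matrices of the same dimension", call. = FALSE)
  d <- a - b
  d <- (d + t(d)) / 2
  m <- max(abs(d))
  if (m == 0) return(TRUE)
  ev <- eigen(d, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -1e-10 * m
}
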
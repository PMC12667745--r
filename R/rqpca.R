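#' Rayleigh-quotient contrastive PCA
#'
#' Fits the contrastive dimension reduction that maximizes the ratio of
#' target variance to background variance,
#' \deqn{\rho(v) = \frac{v^\top \hat\Sigma_T v}{v^\top \hat\Sigma_B v},}
#' exactly, via the generalized eigenproblem
#' \eqn{\hat\Sigma_T v = \lambda (\hat\Sigma_B + \mu I) v}. The leading
#' generalized eigenvector (GE 1) is the axis with the most target-specific
#' variance after accounting for background variance; eigenvalue
#' \eqn{\lambda_i} is the target/background variance ratio along GE i. There
#' is no contrast parameter to tune, unlike cPCA ([cpca()]).
#'
#' Inputs are two data matrices (observations x features with shared feature
#' columns) or a precomputed [cov_pair]. With `scale. = TRUE` (default) each
#' matrix is standard-scaled separately, so the covariances are correlation
#' matrices and loadings group correlated features. Ordinary PCA is the
#' special case of an identity background: `rqpca(x, background = NULL)`
#' contrasts against the identity and reduces to PCA of the (scaled) target.
#'
#' @param target Data matrix (observations x features), or a [cov_pair] (in
#'   which case `background` must be omitted and no scores are produced).
#' @param background Data matrix over the same features, or `NULL` to
#'   contrast against the identity (ordinary PCA of the target).
#' @param d Number of generalized eigenvectors to retain.
#' @param mu Tikhonov shrinkage of the background, or `"auto"` (default):
#'   zero when the background is positive definite, else a small scale-aware
#'   shift; see [solve_rho_pca()].
#' @param scale. Standard-scale each data matrix separately before computing
#'   covariances.
#' @param labels_target,labels_background Optional per-observation group
#'   labels (e.g. cell types) used to compute per-group projected variance
#'   ratios; see [group_variance_ratios()].
#' @return Object of class `rqpca`: the [solve_rho_pca()] solution plus
#'   `scores_t`, `scores_b` (projections of the scaled data on the GEs),
#'   `group_ratios` (when labels were given), `pair`, `scaling` (per-group
#'   centers/scales), and `call`. Methods: `print`, `summary`, `coef`
#'   (loadings), `predict` (project new data), `plot` (score scatter),
#'   `screeplot`.
#' @examples
#' sim <- simulate_contrastive(n_t = 300, n_b = 300, dim = 10, seed = 7)
#' fit <- rqpca(sim$target, sim$background, d = 2, scale. = FALSE)
#' fit$values                      # variance ratios along GE 1, GE 2
#' abs(cor(coef(fit)[, 1], sim$axes$unique[, 1]))
#' @export
rqpca <- function(target, background = NULL, d = 2, mu = "auto", scale. = TRUE,
                  labels_target = NULL, labels_background = NULL) {
  cl <- match.call()
  scaling <- NULL
  if (inherits(target, "cov_pair")) {
    if (!is.null(background))
      stop("`background` must be omitted when `target` is a cov_pair", call. = FALSE)
    pair <- target
    xt <- xb <- NULL
  } else {
    xt <- as_num_matrix(target, "target")
    if (is.null(background)) {
      xb <- NULL
      if (scale.) xt <- standard_scale(xt)
      pair <- cov_pair(sample_covariance(xt), diag(ncol(xt)),
                       feature_names = colnames(xt), n_t = nrow(xt))
    } else {
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
    if (scale.)
      scaling <- list(
        target = list(center = attr(xt, "center"), scale = attr(xt, "scale")),
        background = if (!is.null(xb))
          list(center = attr(xb, "center"), scale = attr(xb, "scale")))
  }

  sol <- solve_rho_pca(pair, d = d, mu = mu)
  out <- unclass(sol)
  out$pair <- pair
  out$scaling <- scaling
  out$call <- cl
  if (!is.null(xt)) out$scores_t <- project(xt, sol)
  if (!is.null(xb)) out$scores_b <- project(xb, sol)
  if (!is.null(labels_target) && !is.null(labels_background)) {
    if (is.null(xt) || is.null(xb))
      stop("group ratios require data matrices, not a cov_pair", call. = FALSE)
    out$group_ratios <- group_variance_ratios(out$scores_t, out$scores_b,
                                              labels_target, labels_background)
  }
  structure(out, class = c("rqpca", "rq_solution"))
}

#' @export
print.rqpca <- function(x, ...) {
  cat("Rayleigh-quotient contrastive PCA\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d features, %d components, mu = %.3g%s\n",
              x$dim, x$d, x$mu, if (isTRUE(x$auto_mu)) " (auto)" else ""))
  cat("Target/background variance ratios (generalized eigenvalues):\n")
  print(signif(x$values, 5))
  invisible(x)
}

#' @export
summary.rqpca <- function(object, k = 5, ...) {
  structure(
    list(call = object$call, dim = object$dim, d = object$d, mu = object$mu,
         auto_mu = object$auto_mu, values = object$values,
         top = top_loadings(object, k = min(k, object$dim)),
         group_ratios = object$group_ratios,
         n_t = object$pair$n_t, n_b = object$pair$n_b),
    class = "summary.rqpca")
}

#' @export
print.summary.rqpca <- function(x, ...) {
  cat("Rayleigh-quotient contrastive PCA\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Features: %d   components retained: %d   mu: %.3g%s\n",
              x$dim, x$d, x$mu, if (isTRUE(x$auto_mu)) " (auto)" else ""))
  if (!is.null(x$n_t))
    cat(sprintf("Samples: target %d, background %s\n", x$n_t, x$n_b %||% "-"))
  cat("\nGeneralized eigenvalues (target/background variance ratio):\n")
  print(signif(x$values, 5))
  cat("\nTop loadings per component:\n")
  print(x$top, row.names = FALSE)
  if (!is.null(x$group_ratios)) {
    cat("\nPer-group target/background variance ratios:\n")
    print(x$group_ratios, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.rqpca <- function(object, ...) object$vectors

#' Project new data onto fitted generalized eigenvectors
#'
#' Applies the scaling stored at fit time (per the `group` the new data
#' belongs to) and projects onto the fitted components. With `scale = FALSE`
#' at fit time, or `group = "none"`, the data is projected as-is.
#'
#' @param object A fitted `rqpca` object.
#' @param newdata Matrix (observations x features) over the fitted features.
#' @param group Which stored scaling to apply: `"target"`, `"background"`,
#'   or `"none"`.
#' @param ... Unused.
#' @return Score matrix (observations x d).
#' @export
predict.rqpca <- function(object, newdata,
                          group = c("target", "background", "none"), ...) {
  group <- match.arg(group)
  x <- as_num_matrix(newdata, "newdata")
  if (group != "none" && !is.null(object$scaling)) {
    sc <- object$scaling[[group]]
    if (is.null(sc))
      stop(sprintf("no stored scaling for group '%s'", group), call. = FALSE)
    scl <- ifelse(is.na(sc$scale), 1, sc$scale)
    x <- sweep(sweep(x, 2, sc$center, `-`), 2, scl, `/`)
  }
  project(x, object)
}

#' @export
plot.rqpca <- function(x, components = c(1, 2), ...) {
  if (is.null(x$scores_t))
    stop("no scores stored (fit was on a cov_pair); use predict()", call. = FALSE)
  i <- components[1]; j <- components[min(2, length(components))]
  st <- x$scores_t[, c(i, j), drop = FALSE]
  sb <- x$scores_b
  xlim <- range(st[, 1], if (!is.null(sb)) sb[, i])
  ylim <- range(st[, 2], if (!is.null(sb)) sb[, j])
  plot(st[, 1], st[, 2], col = "#1f77b4", pch = 16, cex = 0.6,
       xlab = sprintf("GE %d", i), ylab = sprintf("GE %d", j),
       xlim = xlim, ylim = ylim, ...)
  if (!is.null(sb))
    graphics::points(sb[, i], sb[, j], col = "#d62728", pch = 17, cex = 0.6)
  graphics::legend("topright", legend = c("target", "background"),
                   col = c("#1f77b4", "#d62728"), pch = c(16, 17), bty = "n")
  invisible(x)
}

#' @importFrom stats screeplot
#' @export
screeplot.rqpca <- function(x, ...) {
  graphics::barplot(x$values, names.arg = names(x$values),
                    ylab = "target/background variance ratio", ...)
  invisible(x)
}
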
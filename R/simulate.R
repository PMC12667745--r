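#' Simulate a planted-axis contrastive scenario
#'
#' Draws mean-zero multivariate Gaussian target and background samples whose
#' population covariances share variance along a set of common axes while the
#' target carries additional variance along unique orthogonal axes. Along the
#' remaining dimensions both populations have isotropic noise; unique axes
#' carry only noise-level variance in the background. The default scenario is
#' 30 dimensions, two shared axes (variance 10 in both groups), one unique
#' axis (variance 10, target only), noise variance 1, and 1,000 samples per
#' group — the unique axis then ties the shared axes in target variance, so
#' plain PCA of the target has no margin to find it, while its
#' target/background variance ratio (10) far exceeds the shared axes' (1).
#'
#' With `noise_var = 0` the background covariance is rank-deficient,
#' exercising the automatic Tikhonov regularization path end-to-end.
#'
#' @param n_t,n_b Samples per group.
#' @param dim Ambient dimension D.
#' @param shared_var_target,shared_var_background Variances along the shared
#'   axes (equal length; one entry per shared axis).
#' @param unique_var Variances along target-only axes (one entry per axis).
#' @param noise_var Isotropic noise variance on the remaining dimensions
#'   (and the background's variance along the unique axes).
#' @param axes Optional D x (n_shared + n_unique) matrix of orthonormal axis
#'   columns, shared axes first. Random orthonormal axes are drawn when
#'   omitted. Non-orthonormal axes are an error.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return List: `target` (n_t x D), `background` (n_b x D), `axes`
#'   (`$shared`, `$unique` matrices of axis columns), `sigma_t_pop`,
#'   `sigma_b_pop` (population covariances), and the scenario parameters.
#' @export
simulate_contrastive <- function(n_t = 1000, n_b = 1000, dim = 30,
                                 shared_var_target = c(10, 10),
                                 shared_var_background = c(10, 10),
                                 unique_var = 10, noise_var = 1,
                                 axes = NULL, seed = 1) {
  n_s <- length(shared_var_target)
  n_u <- length(unique_var)
  if (length(shared_var_background) != n_s)
    stop("shared variance vectors must have equal length", call. = FALSE)
  if (any(c(shared_var_target, shared_var_background, unique_var) <= 0))
    stop("axis variances must be positive", call. = FALSE)
  if (noise_var < 0) stop("`noise_var` must be nonnegative", call. = FALSE)
  if (n_s + n_u > dim) stop("more planted axes than dimensions", call. = FALSE)

  local_seed(seed, {
    if (is.null(axes)) {
      axes <- random_orthonormal(dim, n_s + n_u)
    } else {
      axes <- as_num_matrix(axes, "axes")
      if (nrow(axes) != dim || ncol(axes) != n_s + n_u)
        stop(sprintf("`axes` must be %d x %d", dim, n_s + n_u), call. = FALSE)
      gram <- crossprod(axes)
      if (max(abs(gram - diag(ncol(axes)))) > 1e-8)
        stop("planted axes must be mutually orthogonal unit vectors", call. = FALSE)
    }
    shared <- axes[, seq_len(n_s), drop = FALSE]
    uniq <- axes[, n_s + seq_len(n_u), drop = FALSE]

    proj <- tcrossprod(axes)                       # projector onto planted axes
    base <- noise_var * (diag(dim) - proj)
    sigma_t <- base + shared %*% (shared_var_target * t(shared)) +
      uniq %*% (unique_var * t(uniq))
    sigma_b <- base + shared %*% (shared_var_background * t(shared)) +
      uniq %*% (noise_var * diag(n_u)) %*% t(uniq)
    sigma_t <- (sigma_t + t(sigma_t)) / 2
    sigma_b <- (sigma_b + t(sigma_b)) / 2

    st <- sym_sqrt(sigma_t); sb <- sym_sqrt(sigma_b)
    target <- matrix(stats::rnorm(n_t * dim), n_t, dim) %*% st
    background <- matrix(stats::rnorm(n_b * dim), n_b, dim) %*% sb
    colnames(target) <- colnames(background) <- paste0("f", seq_len(dim))

    list(target = target, background = background,
         axes = list(shared = shared, unique = uniq),
         sigma_t_pop = sigma_t, sigma_b_pop = sigma_b,
         params = list(n_t = n_t, n_b = n_b, dim = dim,
                       shared_var_target = shared_var_target,
                       shared_var_background = shared_var_background,
                       unique_var = unique_var, noise_var = noise_var,
                       seed = seed))
  })
}

#' Simulate overdispersed count matrices for the preprocessing chain
#'
#' Generates two Gamma–Poisson (negative-binomial-like) count matrices with
#' log-normal per-cell depth variation and log-normal gene base means,
#' structurally emulating UMI count data (sparsity, overdispersion). A chosen
#' set of planted genes forms a correlated module in the target group only:
#' those genes share a per-cell log-normal latent factor, giving them extra,
#' mutually correlated variability that survives per-gene standard scaling —
#' the kind of target-specific co-variation the contrastive method is
#' designed to find (after scaling, covariances are correlation matrices and
#' generalized eigenvectors pick out modules of correlated genes). Fully
#' reproducible from `seed`.
#'
#' @param n_per_group Cells per group.
#' @param n_genes Number of genes.
#' @param planted_genes Character vector of gene names (subset of
#'   `gene1..geneG`) forming the target-only variable module, or an integer
#'   count of genes to plant (the first that many genes).
#' @param seed Integer seed.
#' @param dispersion Baseline Gamma dispersion (1/shape).
#' @param planted_factor Strength of the planted module: the shared latent
#'   factor has log-scale standard deviation `log(planted_factor) / 2`
#'   (1 = no planted signal).
#' @param depth_sd SD of log depth factors across cells.
#' @param groups Optional number of cell subpopulations per side; cells are
#'   labelled `grp1..grpK` and the planted module is active only in `grp1`
#'   cells when `K > 1`.
#' @return List: `target`, `background` (integer matrices, cells x genes,
#'   named), `labels_t`, `labels_b`, `planted_genes`.
#' @export
simulate_counts <- function(n_per_group = 500, n_genes = 500,
                            planted_genes = 10, seed = 1,
                            dispersion = 0.5, planted_factor = 10,
                            depth_sd = 0.5, groups = 1) {
  genes <- paste0("gene", seq_len(n_genes))
  if (is.numeric(planted_genes) && length(planted_genes) == 1L)
    planted_genes <- genes[seq_len(planted_genes)]
  if (!all(planted_genes %in% genes))
    stop("`planted_genes` must be a subset of the gene set", call. = FALSE)
  planted <- genes %in% planted_genes

  local_seed(seed, {
    base_mean <- exp(stats::rnorm(n_genes, log(1.5), 1))
    module_sd <- log(max(planted_factor, 1)) / 2
    draw <- function(n, prefix, hot_rows = NULL) {
      depth <- exp(stats::rnorm(n, 0, depth_sd))
      mu <- outer(depth, base_mean)
      if (!is.null(hot_rows) && any(planted) && module_sd > 0) {
        latent <- exp(stats::rnorm(length(hot_rows), 0, module_sd) - module_sd^2 / 2)
        mu[hot_rows, planted] <- mu[hot_rows, planted] * latent
      }
      lam <- mu * matrix(stats::rgamma(n * n_genes, shape = 1 / dispersion,
                                       scale = dispersion), n, n_genes)
      m <- matrix(stats::rpois(n * n_genes, lam), n, n_genes)
      dimnames(m) <- list(paste0(prefix, seq_len(n)), genes)
      m
    }
    k <- max(1L, as.integer(groups))
    lab <- function(n) paste0("grp", rep_len(seq_len(k), n))
    labels_t <- lab(n_per_group); labels_b <- lab(n_per_group)
    hot <- if (k > 1) which(labels_t == "grp1") else seq_len(n_per_group)
    target <- draw(n_per_group, "t", hot)
    background <- draw(n_per_group, "b")
    list(target = target, background = background,
         labels_t = labels_t, labels_b = labels_b,
         planted_genes = planted_genes)
  })
}

#' Random symmetric positive-definite covariance pair
#'
#' Property-test input generator: two independent random SPD matrices with
#' eigenvalue condition number at most `condition`, each with a random
#' orthonormal eigenbasis and a random overall scale. With `condition = 1`
#' both matrices are positive multiples of the identity.
#'
#' @param dim Dimension (>= 1).
#' @param condition Upper bound on each matrix's condition number (>= 1).
#' @param seed Integer seed.
#' @return A [cov_pair].
#' @export
random_spd_pair <- function(dim, condition = 10, seed = 1) {
  if (dim < 1) stop("`dim` must be >= 1", call. = FALSE)
  if (condition < 1) stop("`condition` must be >= 1", call. = FALSE)
  local_seed(seed, {
    one <- function() {
      q <- random_orthonormal(dim)
      ev <- if (condition == 1) rep(1, dim) else {
        e <- stats::runif(dim, 1, condition)
        # pin the extremes so the condition bound is tight but never exceeded
        e[1] <- 1; if (dim > 1) e[2] <- condition
        e
      }
      s <- exp(stats::rnorm(1, 0, 0.5))
      m <- q %*% (s * ev * t(q))
      (m + t(m)) / 2
    }
    cov_pair(one(), one())
  })
}
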
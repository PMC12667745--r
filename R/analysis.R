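#' Project data onto generalized eigenvectors
#'
#' Returns the score matrix \eqn{X V}: column i holds the projections onto
#' the i-th generalized eigenvector. The data must be over the same features,
#' scaled with the same per-group convention used to form the covariances;
#' name divergence is an error, never silent reindexing.
#'
#' When covariances and scores come from the same centered matrices, the
#' pooled variance ratio of target to background scores on component i
#' equals the eigenvalue \eqn{\lambda_i} — the interpretability identity
#' \eqn{v_i^\top\hat\Sigma_T v_i / v_i^\top\hat\Sigma_B v_i = \lambda_i}.
#'
#' @param data Matrix (observations x features).
#' @param sol An `rq_solution` (or `rqpca` fit).
#' @return Score matrix (observations x d) with component column names.
#' @export
project <- function(data, sol) {
  stopifnot(inherits(sol, "rq_solution"))
  x <- as_num_matrix(data, "data")
  if (ncol(x) != sol$dim)
    stop(sprintf("data has %d features but the solution has %d", ncol(x), sol$dim),
         call. = FALSE)
  if (!is.null(colnames(x)) && !identical(colnames(x), rownames(sol$vectors))) {
    i <- which(colnames(x) != rownames(sol$vectors))[1]
    stop(sprintf("feature names diverge at column %d: '%s' vs '%s'",
                 i, colnames(x)[i], rownames(sol$vectors)[i]), call. = FALSE)
  }
  x %*% sol$vectors
}

#' Per-group projected variance ratios
#'
#' For every group present in both label sets and every component, computes
#' the ratio of target-score variance to background-score variance (sample
#' variance, denominator n - 1). This is the per-group Rayleigh quotient of
#' each generalized eigenvector: the group with the largest GE-1 ratio is the
#' one driving the main axis of target-specific variation. Groups with fewer
#' than 2 members on either side get `NA` ratios (never 0 or Inf) and are
#' flagged.
#'
#' @param scores_t,scores_b Score matrices from [project()].
#' @param labels_t,labels_b Group labels, one per row of the score matrices.
#' @return Data frame with columns `group`, `component`, `n_target`,
#'   `n_background`, `var_target`, `var_background`, `ratio` (target over
#'   background), `defined`.
#' @export
group_variance_ratios <- function(scores_t, scores_b, labels_t, labels_b) {
  scores_t <- as_num_matrix(scores_t, "scores_t")
  scores_b <- as_num_matrix(scores_b, "scores_b")
  labels_t <- as.character(labels_t)
  labels_b <- as.character(labels_b)
  if (length(labels_t) != nrow(scores_t) || length(labels_b) != nrow(scores_b))
    stop("labels must cover every row of the score matrices", call. = FALSE)
  shared <- intersect(unique(labels_t), unique(labels_b))
  if (length(shared) == 0)
    stop("target and background label sets are disjoint", call. = FALSE)
  d <- ncol(scores_t)
  comp <- colnames(scores_t) %||% paste0("GE", seq_len(d))
  rows <- list()
  for (g in shared) {
    it <- labels_t == g; ib <- labels_b == g
    nt <- sum(it); nb <- sum(ib)
    for (j in seq_len(d)) {
      vt <- if (nt >= 2) stats::var(scores_t[it, j]) else NA_real_
      vb <- if (nb >= 2) stats::var(scores_b[ib, j]) else NA_real_
      ratio <- if (!is.na(vt) && !is.na(vb) && vb > 0) vt / vb else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, component = comp[j], n_target = nt, n_background = nb,
        var_target = vt, var_background = vb, ratio = ratio,
        defined = !is.na(ratio))
    }
  }
  do.call(rbind, rows)
}

#' Top loadings per component
#'
#' Ranks features by absolute loading within each component, reporting the
#' signed values. Under the fixed sign convention (largest-magnitude entry of
#' each eigenvector positive) the table is deterministic; ties in magnitude
#' are broken by original feature order.
#'
#' @param sol An `rq_solution` or `rqpca` fit.
#' @param k Number of features to report per component.
#' @return Data frame with columns `component`, `rank`, `feature`, `loading`.
#' @export
top_loadings <- function(sol, k = 10) {
  stopifnot(inherits(sol, "rq_solution"))
  if (k < 1 || k > sol$dim)
    stop(sprintf("`k` must be in 1..%d", sol$dim), call. = FALSE)
  v <- sol$vectors
  out <- lapply(seq_len(ncol(v)), function(j) {
    ord <- order(-abs(v[, j]), seq_len(nrow(v)))[seq_len(k)]
    data.frame(component = colnames(v)[j], rank = seq_len(k),
               feature = rownames(v)[ord], loading = v[ord, j],
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Write / read a projection report directory
#'
#' `write_report()` serializes a fitted `rqpca` (or `cpca`) model as a
#' directory of named CSV files: `scores_target.csv`, `scores_background.csv`,
#' `loadings.csv`, `eigenvalues.csv`, and `group_ratios.csv` when per-group
#' ratios were computed. Ratio orientation is target over background
#' throughout. `read_report()` loads the directory back into a list of the
#' same pieces; a write/read round trip is lossless up to float formatting.
#'
#' @param fit A fitted `rqpca` or `cpca` object with stored scores.
#' @param dir Output directory (created if needed).
#' @param digits Significant digits written (default 15, round-trip safe).
#' @return `write_report()`: `dir`, invisibly. `read_report()`: list with
#'   `scores_t`, `scores_b`, `loadings`, `values`, `mu`, `group_ratios`.
#' @export
write_report <- function(fit, dir, digits = 15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = digits)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  }
  sc_t <- fit$scores_t
  if (is.null(sc_t)) stop("fit has no stored scores", call. = FALSE)
  wcsv(data.frame(sample = rownames(sc_t) %||% seq_len(nrow(sc_t)), sc_t,
                  check.names = FALSE), "scores_target.csv")
  if (!is.null(fit$scores_b))
    wcsv(data.frame(sample = rownames(fit$scores_b) %||% seq_len(nrow(fit$scores_b)),
                    fit$scores_b, check.names = FALSE), "scores_background.csv")
  wcsv(data.frame(feature = rownames(fit$vectors), fit$vectors,
                  check.names = FALSE), "loadings.csv")
  wcsv(data.frame(component = names(fit$values), lambda = unname(fit$values),
                  mu = fit$mu %||% NA_real_, alpha = fit$alpha %||% NA_real_),
       "eigenvalues.csv")
  if (!is.null(fit$group_ratios)) wcsv(fit$group_ratios, "group_ratios.csv")
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, check.names = FALSE) else NULL
  }
  to_mat <- function(df) {
    if (is.null(df)) return(NULL)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  ev <- rd("eigenvalues.csv")
  list(scores_t = to_mat(rd("scores_target.csv")),
       scores_b = to_mat(rd("scores_background.csv")),
       loadings = to_mat(rd("loadings.csv")),
       values = stats::setNames(ev$lambda, ev$component),
       mu = ev$mu[1],
       group_ratios = rd("group_ratios.csv"))
}
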
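# Preprocessing chain: counts -> filtered -> depth-normalized/log1p ->
# highly-variable subset -> per-group standard scaling -> covariance.
# Rows are observations (cells/samples), columns are features (genes)
# everywhere in this package.

# Error unless two matrices carry identical feature columns; names the first
# divergent feature instead of silently reindexing.
align_features <- function(a, b) {
  if (ncol(a) != ncol(b))
    stop(sprintf("feature dimension mismatch: %d vs %d columns", ncol(a), ncol(b)),
         call. = FALSE)
  na <- colnames(a); nb <- colnames(b)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb)) {
    i <- which(na != nb)[1]
    stop(sprintf("feature names diverge at column %d: '%s' vs '%s'", i, na[i], nb[i]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Filter features by total count percentile
#'
#' Keeps features whose total count across all observations is at or above
#' the given percentile of the per-feature totals (default the 80th
#' percentile, the high-expression filter used before highly-variable-gene
#' selection). The percentile is computed by linear interpolation between
#' order statistics and the comparison is inclusive, so features tied exactly
#' at the threshold are kept. Column order is preserved.
#'
#' @param counts Nonnegative matrix, observations x features.
#' @param percentile Percentile in `[0, 100)` of feature totals.
#' @return The matrix restricted to the kept feature columns, with attribute
#'   `"threshold"` (the count cutoff).
#' @examples
#' m <- matrix(rep(1:10, each = 2), nrow = 2,
#'             dimnames = list(NULL, paste0("g", 1:10)))
#' colnames(filter_high_expression(m, 80))  # totals >= 16.4: g9, g10
#' @export
filter_high_expression <- function(counts, percentile = 80) {
  counts <- as_num_matrix(counts, "counts")
  if (nrow(counts) == 0 || ncol(counts) == 0)
    stop("`counts` must have at least one row and one column", call. = FALSE)
  if (any(counts < 0)) stop("`counts` must be nonnegative", call. = FALSE)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile < 0 || percentile >= 100)
    stop("`percentile` must be a single value in [0, 100)", call. = FALSE)
  totals <- colSums(counts)
  thr <- unname(stats::quantile(totals, percentile / 100, type = 7))
  keep <- totals >= thr
  out <- counts[, keep, drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Depth-normalize rows and apply log1p
#'
#' Rescales each observation (row) so its total equals `target_sum` (default
#' 10,000, the usual UMI depth normalization), then applies `log1p`
#' elementwise. Observations with zero total are an error, reported by name.
#'
#' @param counts Nonnegative matrix, observations x features.
#' @param target_sum Row total after normalization.
#' @return The transformed matrix with attributes `"depth_normalized"` and
#'   `"logged"` set to `TRUE`.
#' @export
depth_normalize_log1p <- function(counts, target_sum = 10000) {
  counts <- as_num_matrix(counts, "counts")
  if (any(counts < 0)) stop("`counts` must be nonnegative", call. = FALSE)
  rs <- rowSums(counts)
  if (any(rs <= 0)) {
    bad <- which(rs <= 0)
    nm <- rownames(counts)[bad] %||% as.character(bad)
    stop(sprintf("empty observations (zero total counts): %s",
                 paste(utils::head(nm, 5), collapse = ", ")), call. = FALSE)
  }
  out <- log1p(counts * (target_sum / rs))
  attr(out, "depth_normalized") <- TRUE
  attr(out, "logged") <- TRUE
  out
}

#' Select highly variable features by binned normalized dispersion
#'
#' For each feature of a log-normalized matrix, computes the mean and the
#' dispersion (variance over mean) across observations; features are then
#' grouped into `n_bins` equal-count bins by mean expression, dispersions are
#' z-scored within each bin, and the `n_top` features with the highest
#' normalized dispersion are returned. Features with zero mean have
#' dispersion defined as 0; a bin with a single member (or zero dispersion
#' spread) gets z-scores of 0. Ties in normalized dispersion are broken by
#' original column order.
#'
#' @param x Matrix of log-normalized values, observations x features.
#' @param n_top Number of features to select (<= number of features).
#' @param n_bins Number of equal-count mean bins.
#' @return Character vector of the selected feature names in original column
#'   order, with attribute `"stats"`: a data frame of per-feature `mean`,
#'   `dispersion`, `bin`, `normalized_dispersion`, `selected`.
#' @export
select_highly_variable <- function(x, n_top = 2000, n_bins = 20) {
  x <- as_num_matrix(x, "x")
  G <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(G))
  if (!is.numeric(n_top) || length(n_top) != 1L || n_top < 1 || n_top > G)
    stop(sprintf("`n_top` must be an integer in 1..%d (got %s)", G, n_top),
         call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 observations", call. = FALSE)

  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)

  n_bins <- max(1L, min(as.integer(n_bins), G))
  # equal-count bins on the rank of the mean
  bin <- as.integer(cut(rank(mu, ties.method = "first"),
                        breaks = n_bins, labels = FALSE, include.lowest = TRUE))
  z <- numeric(G)
  for (b in unique(bin)) {
    idx <- which(bin == b)
    if (length(idx) < 2) { z[idx] <- 0; next }
    s <- stats::sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  ord <- order(-z, seq_len(G))
  sel_idx <- sort(ord[seq_len(n_top)])
  stats_df <- data.frame(feature = colnames(x), mean = mu, dispersion = disp,
                         bin = bin, normalized_dispersion = z,
                         selected = seq_len(G) %in% sel_idx,
                         row.names = NULL)
  out <- colnames(x)[sel_idx]
  attr(out, "stats") <- stats_df
  out
}

#' Standard-scale columns to mean 0, variance 1
#'
#' Centers each column and divides by its sample standard deviation
#' (denominator `n - 1`, matching [sample_covariance()], so the covariance of
#' a scaled matrix has exactly unit diagonal and is a correlation matrix).
#' Constant columns cannot be scaled; they are set to all zeros and reported
#' with a warning.
#'
#' @param x Numeric matrix with at least 2 rows.
#' @return Scaled matrix with attributes `"center"`, `"scale"` (per-column)
#'   and `"scaled" = TRUE`.
#' @export
standard_scale <- function(x) {
  x <- as_num_matrix(x, "x")
  if (nrow(x) < 2) stop("`x` must have at least 2 rows to scale", call. = FALSE)
  ctr <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  const <- sdev == 0 | is.na(sdev)
  if (any(const)) {
    nm <- colnames(x)[const] %||% as.character(which(const))
    warning(sprintf("constant columns set to zero: %s",
                    paste(utils::head(nm, 5), collapse = ", ")), call. = FALSE)
  }
  scl <- ifelse(const, 1, sdev)
  out <- sweep(sweep(x, 2, ctr, `-`), 2, scl, `/`)
  out[, const] <- 0
  attr(out, "center") <- ctr
  attr(out, "scale") <- ifelse(const, NA_real_, sdev)
  attr(out, "scaled") <- TRUE
  out
}

#' Sample covariance of a data matrix
#'
#' \eqn{\hat\Sigma = X_c^\top X_c / (n - 1)} on column-centered data. For a
#' standard-scaled input the result is the correlation matrix (unit
#' diagonal), so downstream eigenvectors can be read as modules of
#' correlated features.
#'
#' @param x Numeric matrix (observations x features), at least 2 rows.
#' @return Symmetric feature x feature covariance matrix.
#' @export
sample_covariance <- function(x) {
  x <- as_num_matrix(x, "x")
  if (nrow(x) < 2)
    stop("`x` must have at least 2 rows to estimate a covariance", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x), `-`)
  s <- crossprod(xc) / (nrow(x) - 1)
  (s + t(s)) / 2
}
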
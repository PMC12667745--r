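test_that("projection is X V with strict feature alignment", {
  sol <- solve_rho_pca(cov_pair(diag(c(3, 2, 1)), diag(3)))
  x <- matrix(stats::rnorm(30), 10, 3, dimnames = list(NULL, paste0("f", 1:3)))
  expect_equal(project(x, sol), x %*% sol$vectors, ignore_attr = TRUE)
  # identity-block eigenvectors return the original coordinates
  expect_equal(unname(project(x, sol)), unname(x[, c(1, 2, 3)]))

  colnames(x) <- c("f1", "wrong", "f3")
  expect_error(project(x, sol), "diverge at column 2")
  expect_error(project(x[, 1:2], sol), "features")
})

test_that("pooled projected-variance ratio on GE i equals lambda_i", {
  sim <- simulate_contrastive(n_t = 300, n_b = 250, dim = 12, seed = 8,
                              shared_var_target = c(10, 10),
                              shared_var_background = c(10, 10))
  xt <- scale(sim$target, scale = FALSE)
  xb <- scale(sim$background, scale = FALSE)
  pair <- cov_pair(sample_covariance(xt), sample_covariance(xb))
  sol <- solve_rho_pca(pair, d = 4)
  st <- project(xt, sol); sb <- project(xb, sol)
  for (j in 1:4) {
    ratio <- stats::var(st[, j]) / stats::var(sb[, j])
    expect_lt(abs(ratio - sol$values[j]), 1e-6 * (1 + sol$values[j]))
  }
})

test_that("per-group variance ratios handle identical groups, identities and small groups", {
  s <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, paste0("GE", 1:3)))
  lab <- rep(c("a", "b"), 10)
  r <- group_variance_ratios(s, s, lab, lab)
  expect_equal(r$ratio, rep(1, 6))
  expect_true(all(r$defined))

  # single shared group spanning all rows reproduces the eigenvalue identity
  sim <- simulate_contrastive(n_t = 200, n_b = 200, dim = 6, seed = 2,
                              shared_var_target = 8, shared_var_background = 8)
  xt <- scale(sim$target, scale = FALSE); xb <- scale(sim$background, scale = FALSE)
  pair <- cov_pair(sample_covariance(xt), sample_covariance(xb))
  sol <- solve_rho_pca(pair, d = 2)
  r2 <- group_variance_ratios(project(xt, sol), project(xb, sol),
                              rep("all", 200), rep("all", 200))
  expect_equal(r2$ratio, unname(sol$values), tolerance = 1e-6)

  # groups with < 2 members on either side are NA, never 0 or Inf
  r3 <- group_variance_ratios(s, s, c("solo", rep("a", 19)),
                              c(rep("a", 19), "solo"))
  expect_true(all(is.na(r3$ratio[r3$group == "solo"])))
  expect_false(any(r3$defined[r3$group == "solo"]))

  expect_error(group_variance_ratios(s, s, rep("x", 20), rep("y", 20)),
               "disjoint")
  expect_error(group_variance_ratios(s, s, "x", rep("x", 20)), "every row")
})

test_that("a group with planted target-only variance has the top GE-1 ratio", {
  sim <- simulate_counts(n_per_group = 450, n_genes = 80, planted_genes = 10,
                         seed = 11, groups = 3, planted_factor = 25)
  xt <- standard_scale(depth_normalize_log1p(sim$target))
  xb <- standard_scale(depth_normalize_log1p(sim$background))
  fit <- rqpca(xt, xb, d = 2, scale. = FALSE,
               labels_target = sim$labels_t, labels_background = sim$labels_b)
  ge1 <- fit$group_ratios[fit$group_ratios$component == "GE1", ]
  expect_identical(ge1$group[which.max(ge1$ratio)], "grp1")
})

test_that("top_loadings ranks by |loading| with stable ties", {
  sol <- structure(
    list(vectors = matrix(c(0.9, 0.1, 0.3, 0.5, 0.5, -0.5), 3, 2,
                          dimnames = list(c("a", "b", "c"), c("GE1", "GE2"))),
         values = c(GE1 = 2, GE2 = 1), mu = 0, d = 2, dim = 3,
         feature_names = c("a", "b", "c")),
    class = "rq_solution")
  tl <- top_loadings(sol, k = 1)
  expect_identical(tl$feature[tl$component == "GE1"], "a")
  # tied magnitudes resolve in feature order
  expect_identical(tl$feature[tl$component == "GE2"], "a")
  tl3 <- top_loadings(sol, k = 3)
  expect_identical(tl3$feature[tl3$component == "GE2"], c("a", "b", "c"))
  expect_error(top_loadings(sol, k = 9), "1..3")
})

test_that("planted-axis features top GE 1 while shared axes top target PCA", {
  d <- 12
  axes <- diag(d)[, 1:3]  # shared on e1, e2; unique on e3
  sim <- simulate_contrastive(n_t = 800, n_b = 800, dim = d,
                              shared_var_target = c(40, 30),
                              shared_var_background = c(40, 30),
                              unique_var = 10, axes = axes, seed = 4)
  xt <- scale(sim$target, scale = FALSE); xb <- scale(sim$background, scale = FALSE)
  pair <- cov_pair(sample_covariance(xt), sample_covariance(xb))
  ge <- top_loadings(solve_rho_pca(pair, d = 1), k = 1)
  pc <- top_loadings(solve_rho_pca(cov_pair(pair$sigma_t, diag(d)), d = 1), k = 1)
  expect_identical(ge$feature, "f3")
  expect_true(pc$feature %in% c("f1", "f2"))
})

test_that("report directories round-trip losslessly", {
  sim <- simulate_counts(n_per_group = 80, n_genes = 60, planted_genes = 5, seed = 6,
                         groups = 2)
  xt <- standard_scale(depth_normalize_log1p(sim$target))
  xb <- standard_scale(depth_normalize_log1p(sim$background))
  fit <- rqpca(xt, xb, d = 2, scale. = FALSE,
               labels_target = sim$labels_t, labels_background = sim$labels_b)
  dir <- withr::local_tempdir()
  write_report(fit, dir)
  expect_setequal(list.files(dir),
                  c("scores_target.csv", "scores_background.csv", "loadings.csv",
                    "eigenvalues.csv", "group_ratios.csv"))
  back <- read_report(dir)
  expect_equal(back$scores_t, fit$scores_t, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$loadings, fit$vectors, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(back$values), unname(fit$values), tolerance = 1e-12)
  expect_equal(back$group_ratios$ratio, fit$group_ratios$ratio, tolerance = 1e-12)
})
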
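test_that("solver reduces to ordinary PCA with an identity background", {
  s <- solve_rho_pca(cov_pair(diag(c(3, 1)), diag(2)), d = 2)
  expect_equal(unname(s$values), c(3, 1))
  expect_equal(abs(unname(s$vectors)), diag(2), tolerance = 1e-12)
})

test_that("solver matches the closed-form diagonal case with B-normalization", {
  s <- solve_rho_pca(cov_pair(diag(c(8, 2)), diag(c(2, 1))), d = 2)
  expect_equal(unname(s$values), c(4, 2))
  # first vector proportional to (1, 0), normalized so t(v) B v = 1
  expect_equal(unname(s$vectors[, 1]), c(1 / sqrt(2), 0), tolerance = 1e-12)
  expect_equal(unname(s$vectors[, 2]), c(0, 1), tolerance = 1e-12)
})

test_that("solver agrees with the brute-force inverse eigendecomposition oracle", {
  for (s in 1:30) {
    dim <- 2 + (s %% 7)
    pair <- random_spd_pair(dim, condition = 50, seed = 1000 + s)
    sol <- solve_rho_pca(pair)
    orc <- oracle_geigen(pair$sigma_t, pair$sigma_b)
    expect_equal(unname(sol$values), orc$values, tolerance = 1e-8)
    for (j in seq_len(dim)) {
      gap_ok <- all(abs(orc$values[-j] - orc$values[j]) >
                      1e-6 * (1 + abs(orc$values[j])))
      if (gap_ok)
        expect_gt(abs_cos(sol$vectors[, j], orc$vectors[, j]), 1 - 1e-8)
    }
  }
})

test_that("eigenpairs are consistent: lambda_i equals the Rayleigh quotient of v_i", {
  for (s in 1:10) {
    pair <- random_spd_pair(6, condition = 30, seed = 40 + s)
    sol <- solve_rho_pca(pair)
    for (j in 1:6) {
      rho <- rayleigh_quotient(sol$vectors[, j], pair)
      expect_lt(abs(sol$values[j] - rho), 1e-8 * (1 + abs(sol$values[j])))
    }
    expect_true(all(diff(sol$values) <= 1e-12))
  }
})

test_that("eigenvectors are orthonormal in the background inner product", {
  for (s in 1:10) {
    pair <- random_spd_pair(5, condition = 20, seed = 70 + s)
    sol <- solve_rho_pca(pair)
    gram <- t(sol$vectors) %*% pair$sigma_b %*% sol$vectors
    expect_lt(max(abs(gram - diag(5))), 1e-6)
  }
})

test_that("lambda_1 is the variational maximum over a fine 2-D angle grid", {
  theta <- seq(0, pi, length.out = 1801)[-1801]
  for (s in 1:10) {
    pair <- random_spd_pair(2, condition = 25, seed = 200 + s)
    l1 <- solve_rho_pca(pair, d = 1)$values[1]
    grid <- vapply(theta, function(t)
      rayleigh_quotient(c(cos(t), sin(t)), pair), numeric(1))
    expect_true(all(grid <= l1 + 1e-10 * l1))
    expect_lt((l1 - max(grid)) / l1, 1e-4)
  }
})

test_that("scaling either covariance rescales eigenvalues but not the subspace", {
  for (s in 1:10) {
    pair <- random_spd_pair(5, condition = 20, seed = 300 + s)
    a <- 0.5 + 3 * (s / 10); b <- 0.2 + s / 5
    scaled <- cov_pair(a * pair$sigma_t, b * pair$sigma_b)
    s0 <- solve_rho_pca(pair); s1 <- solve_rho_pca(scaled)
    expect_equal(unname(s1$values), unname(s0$values) * a / b, tolerance = 1e-8)
    expect_lt(subspace_angle(s0$vectors[, 1:2], s1$vectors[, 1:2]), 1e-8)
    for (j in 1:5) expect_gt(abs_cos(s0$vectors[, j], s1$vectors[, j]), 1 - 1e-8)
  }
})

test_that("the quotient is monotone under the Loewner order", {
  for (s in 1:10) {
    pair <- random_spd_pair(4, condition = 10, seed = 400 + s)
    bump <- random_spd_pair(4, condition = 5, seed = 500 + s)$sigma_t
    bigger_t <- cov_pair(pair$sigma_t + bump, pair$sigma_b)
    bigger_b <- cov_pair(pair$sigma_t, pair$sigma_b + bump)
    expect_true(loewner_dominates(bigger_t$sigma_t, pair$sigma_t))
    vs <- matrix(stats::rnorm(4 * 100), 4)
    for (k in 1:100) {
      v <- vs[, k]
      expect_gte(rayleigh_quotient(v, bigger_t), rayleigh_quotient(v, pair) - 1e-10)
      expect_lte(rayleigh_quotient(v, bigger_b), rayleigh_quotient(v, pair) + 1e-10)
    }
  }
})

test_that("jointly rotating both covariances rotates the eigenvectors", {
  for (s in 1:10) {
    pair <- random_spd_pair(5, condition = 20, seed = 600 + s)
    r <- qr.Q(qr(matrix(stats::rnorm(25), 5)))
    rot <- cov_pair(r %*% pair$sigma_t %*% t(r), r %*% pair$sigma_b %*% t(r))
    s0 <- solve_rho_pca(pair); s1 <- solve_rho_pca(rot)
    expect_equal(unname(s1$values), unname(s0$values), tolerance = 1e-8)
    for (j in 1:5) expect_gt(abs_cos(s1$vectors[, j], r %*% s0$vectors[, j]), 1 - 1e-8)
  }
})

test_that("auto regularization engages only for rank-deficient backgrounds", {
  pd <- random_spd_pair(4, condition = 10, seed = 9)
  expect_identical(solve_rho_pca(pd)$mu, 0)

  # rank-1 background: auto mu is the scale-aware shift, solve succeeds
  b <- tcrossprod(c(1, 1, 0, 0)) * 2
  pair <- cov_pair(pd$sigma_t, b)
  sol <- solve_rho_pca(pair)
  expect_equal(sol$mu, 1e-6 * sum(diag(b)) / 4)
  gram <- t(sol$vectors) %*% (b + diag(sol$mu, 4)) %*% sol$vectors
  expect_lt(max(abs(gram - diag(4))), 1e-6)

  # explicit mu = 0 on a singular background is an error advising regularization
  expect_error(solve_rho_pca(pair, mu = 0), "not positive definite")
  expect_error(solve_rho_pca(pair, mu = -1), "nonnegative")
  expect_error(solve_rho_pca(pair, d = 9), "1..4")
})

test_that("the sign convention makes loadings deterministic", {
  for (s in 1:5) {
    pair <- random_spd_pair(5, condition = 10, seed = 800 + s)
    v <- solve_rho_pca(pair)$vectors
    for (j in 1:5) expect_gt(v[which.max(abs(v[, j])), j], 0)
  }
})

test_that("solutions round-trip through the CSV serialization", {
  pair <- random_spd_pair(4, condition = 10, seed = 31)
  sol <- solve_rho_pca(pair, d = 3)
  dir <- withr::local_tempdir()
  write_solution(sol, dir)
  back <- read_solution(dir)
  expect_equal(back$vectors, sol$vectors, tolerance = 1e-12)
  expect_equal(back$values, sol$values, tolerance = 1e-12)
  expect_equal(back$mu, sol$mu)
})
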
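test_that("degenerate cohorts are handled exactly", {
  ## identical shapes: zero spectrum, mean = the shape
  x <- matrix(rep(c(1, 2, 3, 4, 5, 6), each = 10), 10, 6)
  m <- fit_shape_model(x, 2)
  expect_equal(m$mean, c(1, 2, 3, 4, 5, 6))
  expect_equal(m$eigenvalues, c(0, 0), tolerance = 1e-20)
  ## cohort on an exact 2-D affine subspace: modes 3+ vanish
  set.seed(8)
  base <- rnorm(12)
  w1 <- qr.Q(qr(matrix(rnorm(24), 12, 2)))
  z <- matrix(rnorm(60), 30, 2)
  x2 <- sweep(z %*% t(w1 * rep(c(5, 2), each = 12)), 2, base, "+")
  m2 <- fit_shape_model(x2, 4)
  expect_equal(explained_variance_ratio(m2, 2), 1, tolerance = 1e-12)
  expect_lt(m2$eigenvalues[3], 1e-20)
  expect_lt(max_principal_angle(m2$eigenvectors[, 1:2], w1), 1e-4)
})

test_that("spectrum matches a dense-covariance eigendecomposition oracle", {
  set.seed(9)
  x <- matrix(rnorm(40 * 18), 40, 18)
  m <- fit_shape_model(x, 10)
  oracle <- eigen(cov(x), symmetric = TRUE)$values   # independent route
  expect_equal(m$eigenvalues, oracle[1:10], tolerance = 1e-8)
  expect_equal(m$total_variance, sum(oracle), tolerance = 1e-8)
  ## orthonormality and descending order
  expect_equal(crossprod(m$eigenvectors), diag(10), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  ## sign convention makes the fit reproducible
  expect_identical(m, fit_shape_model(x, 10))
  expect_true(all(apply(m$eigenvectors, 2, function(w) w[which.max(abs(w))] > 0)))
})

test_that("reconstruction evaluates the point-distribution formula exactly", {
  set.seed(10)
  x <- matrix(rnorm(25 * 12), 25, 12)
  m <- fit_shape_model(x, 5)
  expect_equal(reconstruct_shape(m, rep(0, 5)), m$mean)
  e1 <- c(1, rep(0, 4))
  expect_equal(reconstruct_shape(m, e1),
               m$mean + sqrt(m$eigenvalues[1]) * m$eigenvectors[, 1])
  expect_error(reconstruct_shape(m, rep(0, 4)), "length 4")
})

test_that("encode inverts reconstruct and matches a least-squares oracle", {
  set.seed(11)
  x <- matrix(rnorm(20 * 9), 20, 9)
  full <- fit_shape_model(x, 9)          # full rank: min(n-1, d) = 9 < 19
  for (i in c(1, 7, 20))
    expect_equal(reconstruct_shape(full, encode_shape(full, x[i, ])), x[i, ],
                 tolerance = 1e-8)
  expect_equal(encode_shape(full, full$mean), rep(0, 9), tolerance = 1e-10)
  expect_equal(encode_shape(full, reconstruct_shape(full, c(1, rep(0, 8)))),
               c(1, rep(0, 8)), tolerance = 1e-10)
  ## truncated model: projection residual equals the generic LS residual
  m3 <- fit_shape_model(x, 3)
  shape <- x[5, ]
  recon <- reconstruct_shape(m3, encode_shape(m3, shape))
  B <- m3$eigenvectors
  ls <- lm.fit(B, shape - m3$mean)       # independent least-squares route
  expect_equal(sqrt(sum((shape - recon)^2)), sqrt(sum(ls$residuals^2)),
               tolerance = 1e-10)
})

test_that("explained variance ratio is monotone and properly bounded", {
  set.seed(12)
  m <- fit_shape_model(matrix(rnorm(30 * 8), 30, 8), 7)
  evr <- vapply(1:7, function(k) explained_variance_ratio(m, k), numeric(1))
  expect_true(all(diff(evr) >= 0))
  expect_true(all(evr >= 0 & evr <= 1))
  expect_error(explained_variance_ratio(m, 8), "1..7")
  expect_error(fit_shape_model(matrix(rnorm(30 * 8), 30, 8), 9), "at most 8")
})

test_that("a 3-mode latent cohort is recovered above 90% in 3 components", {
  sim <- simulate_shape_cohort(180, dim = 18, n_modes = 3, seed = 21)
  m <- fit_shape_model(sim$shapes, 3)
  expect_gt(explained_variance_ratio(m, 3), 0.90)
  expect_lt(max_principal_angle(m$eigenvectors, sim$modes), 5)
  ## full-rank refit reproduces every training shape
  full <- fit_shape_model(sim$shapes, 18)
  for (i in c(1, 90, 180))
    expect_equal(reconstruct_shape(full, encode_shape(full, sim$shapes[i, ])),
                 sim$shapes[i, ], tolerance = 1e-8)
})

test_that("virtual sampling is seeded, truncated, and centred on the mean", {
  sim <- simulate_shape_cohort(60, dim = 12, n_modes = 3, seed = 3)
  m <- fit_shape_model(sim$shapes, 3)
  s <- sample_virtual_shapes(m, 20, seed = 5)
  expect_identical(dim(s$shapes), c(20L, 12L))
  expect_identical(s, sample_virtual_shapes(m, 20, seed = 5))
  expect_true(all(abs(s$codes) <= 3))
  s0 <- sample_virtual_shapes(m, 4, seed = 5, alpha_bound = 0)
  expect_equal(s0$shapes, matrix(m$mean, 4, 12, byrow = TRUE),
               ignore_attr = TRUE)
  ## sample mean approaches the model mean (3 standard errors per coord)
  big <- sample_virtual_shapes(m, 10000, seed = 6)
  se <- apply(big$shapes, 2, sd) / sqrt(10000)
  expect_true(all(abs(colMeans(big$shapes) - m$mean) < 3 * se + 1e-12))
})
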
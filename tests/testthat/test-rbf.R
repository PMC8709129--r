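test_that("RBF interpolates control points exactly at zero regularization", {
  set.seed(4)
  for (kernel in c("tps", "gaussian", "multiquadric")) {
    src <- matrix(rnorm(18, sd = 5), 6, 3)
    tgt <- src + matrix(rnorm(18, sd = 2), 6, 3)
    d <- fit_rbf(src, tgt, kernel = kernel, shape_parameter = 5)
    expect_lt(max(abs(apply_deformation(d, src) - tgt)), 1e-8)
  }
})

test_that("identity and translation targets are reproduced everywhere", {
  set.seed(5)
  src <- matrix(rnorm(24, sd = 10), 8, 3)
  probe <- matrix(rnorm(30, sd = 20), 10, 3)
  d_id <- fit_rbf(src, src)
  expect_lt(max(abs(d_id$weights)), 1e-10)
  expect_equal(d_id$affine, rbind(0, diag(3)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(apply_deformation(d_id, probe) - probe)), 1e-8)
  t_vec <- c(3, -4, 12)
  d_tr <- fit_rbf(src, sweep(src, 2, t_vec, "+"))
  expect_lt(max(abs(apply_deformation(d_tr, probe) -
                      sweep(probe, 2, t_vec, "+"))), 1e-8)
})

test_that("far-field behavior matches each kernel's analytic structure", {
  set.seed(6)
  src <- matrix(rnorm(18), 6, 3)
  tgt <- src + matrix(rnorm(18, sd = 0.5), 6, 3)
  ## gaussian kernel decays: far field IS the affine part
  dg <- fit_rbf(src, tgt, kernel = "gaussian", shape_parameter = 2)
  far <- matrix(c(500, -800, 300), 1, 3)
  expect_lt(max(abs(apply_deformation(dg, far) - affine_part(dg, far))), 1e-8)
  ## cubic TPS: side constraints cancel the r^3 and r^2 terms, so the
  ## non-affine residual grows at most linearly with distance
  dt <- fit_rbf(src, tgt, kernel = "tps")
  dev_at <- function(r) {
    x <- matrix(c(r, 0.3 * r, -0.7 * r), 1, 3)
    max(abs(apply_deformation(dt, x) - affine_part(dt, x)))
  }
  r1 <- 1e3; r2 <- 1e4
  growth <- dev_at(r2) / dev_at(r1)
  expect_lt(growth, 10 * 1.5)   # linear would be 10; cubic would be 1000
})

test_that("degenerate correspondences raise informative errors", {
  src <- matrix(rnorm(15), 5, 3)
  src[2, ] <- src[4, ]
  expect_error(fit_rbf(src, src, names = c("a", "b", "c", "d", "e")),
               "duplicate.*b/d")
  expect_error(fit_rbf(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3)),
               "at least 4")
  expect_error(fit_rbf(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3),
                       kernel = "cubic"))
  d <- fit_rbf(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3))
  expect_identical(nrow(apply_deformation(d, matrix(numeric(0), 0, 3))), 0L)
})

test_that("morphing to parameters hits the target and preserves topology", {
  tpl <- tpl_small(resolution = 6)
  targets <- list(
    mv_parameters(aml = 27.57, p1 = 15.15, p2 = 17.55, p3 = 14.72,
                  d_am = 21.5, d_ic = 17.65),
    mv_parameters(aml = 13.63, p1 = 6.85, p2 = 8.25, p3 = 6.08,
                  d_am = 23.5, d_ic = 19.65)
  )
  for (tg in targets) {
    m <- morph_to_parameters(tpl, tg)
    expect_lt(max(abs(unclass(measure_parameters(m)) - unclass(tg))), 0.1)
    expect_identical(m$faces, tpl$faces)
    expect_identical(m$chordae, tpl$chordae)
    expect_identical(m$free_edge, tpl$free_edge)
  }
  ## doubling d_ic doubles the measured d_ic
  tg2 <- mv_parameters(aml = 13.63, p1 = 6.85, p2 = 8.25, p3 = 6.08,
                       d_am = 21.5, d_ic = 2 * 17.65)
  expect_equal(measure_parameters(morph_to_parameters(tpl, tg2))[["d_ic"]],
               35.3, tolerance = 1e-6)
  ## self-morph is the identity
  m_self <- morph_to_parameters(tpl, mv_default_parameters())
  expect_lt(max(abs(m_self$vertices - tpl$vertices)), 1e-8)
})

test_that("morphing there and back returns near the original vertices", {
  tpl <- tpl_small(resolution = 5)
  tg <- mv_parameters(aml = 15, p1 = 7.5, p2 = 9, p3 = 6.8,
                      d_am = 22.5, d_ic = 18.5)
  there <- morph_to_parameters(tpl, tg)
  back <- morph_to_parameters(there, mv_default_parameters())
  expect_lt(max(abs(back$vertices - tpl$vertices)), 0.1)
})

test_that("landmark-target morphing moves the named points exactly", {
  tpl <- tpl_small(resolution = 4)
  key <- c("AM_ANT", "AM_POST", "COMM_A", "COMM_P", "ANT_TIP", "P2_TIP")
  tgt <- tpl$vertices[tpl$landmarks[key], ]
  rownames(tgt) <- key
  tgt <- tgt * 1.1
  m <- morph_to_landmarks(tpl, tgt)
  expect_lt(max(abs(m$vertices[m$landmarks[key], ] - tgt)), 1e-8)
  expect_error(morph_to_landmarks(tpl, rbind(NOPE = c(0, 0, 0), tgt)),
               "NOPE")
})
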
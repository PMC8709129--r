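test_that("kinematic invariants evaluate canonical states exactly", {
  f0 <- c(1, 0, 0); t0 <- c(0, 1, 0)
  expect_equal(kinematic_invariants(diag(3), f0, t0),
               c(I1 = 3, I4f = 1, I4t = 1, I8ft = 0, J = 1))
  ## isochoric uniaxial stretch along the fiber
  lam <- 1.2
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  iv <- kinematic_invariants(F, f0, t0)
  expect_equal(iv[["J"]], 1, tolerance = 1e-12)
  expect_equal(iv[["I4f"]], lam^2, tolerance = 1e-12)
  expect_equal(iv[["I8ft"]], 0, tolerance = 1e-14)
  expect_error(kinematic_invariants(diag(c(1, 1, -1)), f0, t0), "inverted")
})

test_that("invariants agree with an explicit tensor-contraction oracle", {
  set.seed(13)
  f0 <- c(1, 0, 0); t0 <- c(0, 1, 0)
  for (i in 1:5) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    if (det(F) <= 0) next
    iv <- kinematic_invariants(F, f0, t0)
    ## oracle: dense contractions on Cbar = J^(-2/3) t(F) F
    J <- det(F)
    Cb <- J^(-2 / 3) * (t(F) %*% F)
    sym_ft <- (outer(f0, t0) + outer(t0, f0)) / 2
    expect_equal(iv[["I1"]], sum(Cb * diag(3)), tolerance = 1e-12)
    expect_equal(iv[["I4f"]], sum(Cb * outer(f0, f0)), tolerance = 1e-12)
    expect_equal(iv[["I4t"]], sum(Cb * outer(t0, t0)), tolerance = 1e-12)
    expect_equal(iv[["I8ft"]], sum(Cb * sym_ft), tolerance = 1e-12)
    expect_equal(iv[["J"]], J, tolerance = 1e-12)
  }
})

test_that("strain energy evaluates the exponential terms as printed", {
  mat <- demo_material()
  at_ref <- strain_energy(diag(3), mat)
  expect_equal(as.numeric(at_ref), mat$a / (2 * mat$b))
  expect_equal(attr(at_ref, "vol"), 0)
  ## without anisotropic moduli only the isotropic exponential remains
  iso <- material_params(a = 20, b = 2.5, a_f = 0, b_f = 1, a_t = 0,
                         b_t = 1, a_ft = 0, b_ft = 1, D = 2e-4)
  lam <- 1.15
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  I1 <- lam^2 + 2 / lam
  expect_equal(as.numeric(strain_energy(F, iso)),
               20 / 5 * exp(2.5 * (I1 - 3)), tolerance = 1e-12)
  expect_error(strain_energy(diag(c(40, 1 / 40, 1)), mat), "overflow")
})

test_that("energy is objective and grows along uniaxial stretch", {
  mat <- demo_material()
  set.seed(14)
  F <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
  for (i in 1:5) {
    Q <- random_rotation(i)
    expect_equal(as.numeric(strain_energy(Q %*% F, mat)),
                 as.numeric(strain_energy(F, mat)), tolerance = 1e-10)
  }
  sweep <- uniaxial_sweep(mat, stretches = seq(1, 1.3, by = 0.05))
  expect_true(all(diff(sweep$energy_kPa) > 0))
  expect_true(all(diff(sweep$sigma_fiber_kPa) > 0))
})

test_that("reference configuration is stress-free for admissible materials", {
  set.seed(15)
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    mat <- material_params(a = runif(1, 1, 50), b = runif(1, 0.5, 5),
                           a_f = runif(1, 0, 200), b_f = runif(1, 1, 15),
                           a_t = runif(1, 0, 80), b_t = runif(1, 1, 10),
                           a_ft = runif(1, 0, 30), b_ft = runif(1, 1, 8),
                           D = runif(1, 1e-5, 1e-3),
                           f0 = q[, 1], t0 = q[, 2])
    expect_lt(max(abs(cauchy_stress(diag(3), mat))), 1e-12)
  }
})

test_that("analytic stress matches central finite differences of the energy", {
  mat <- demo_material()
  set.seed(16)
  for (i in 1:6) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.08), 3, 3)
    if (det(F) <= 0) next
    for (split in c("isochoric", "none")) {
      sig <- cauchy_stress(F, mat, split = split)
      num <- numeric_cauchy_stress(F, mat, split = split)
      expect_equal(sig, num, tolerance = 1e-5)
      expect_equal(sig, t(sig))       # symmetry
    }
  }
})

test_that("pure volumetric response reduces to the pressure term", {
  matv <- material_params(a = 0, b = 1, a_f = 0, b_f = 1, a_t = 0, b_t = 1,
                          a_ft = 0, b_ft = 1, D = 2e-3)
  for (lam in c(0.9, 1.1, 1.25)) {
    J <- lam^3
    expect_equal(cauchy_stress(diag(rep(lam, 3)), matv),
                 (1 / 2e-3) * (J - 1 / J) * diag(3), tolerance = 1e-10)
  }
})

test_that("material parameter validation enforces the admissible set", {
  expect_error(material_params(a = -1, b = 1, a_f = 0, b_f = 1, a_t = 0,
                               b_t = 1, a_ft = 0, b_ft = 1, D = 1e-3), ">= 0")
  expect_error(material_params(a = 1, b = 0, a_f = 0, b_f = 1, a_t = 0,
                               b_t = 1, a_ft = 0, b_ft = 1, D = 1e-3), "> 0")
  expect_error(material_params(a = 1, b = 1, a_f = 0, b_f = 1, a_t = 0,
                               b_t = 1, a_ft = 0, b_ft = 1, D = 1e-3,
                               f0 = c(1, 0, 0), t0 = c(1, 0, 0)), "orthogonal")
})
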
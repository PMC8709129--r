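test_that("projection follows the pinhole-free plane model", {
  vw <- echo_view("v", plane_origin = c(1, 2, 3), basis_u = c(1, 0, 0),
                  basis_v = c(0, 1, 0), pixel_spacing = 0.5)
  at_origin <- project_landmarks(rbind(LM = c(1, 2, 3)), vw, noise_sd = 0)
  expect_equal(c(at_origin$u_px, at_origin$v_px), c(0, 0))
  shifted <- project_landmarks(rbind(LM = c(1, 2, 3) + 3 * 0.5 * c(1, 0, 0)),
                               vw, noise_sd = 0)
  expect_equal(c(shifted$u_px, shifted$v_px), c(3, 0))
  ## empirical click-noise sd over many seeded draws matches noise_sd
  u <- vapply(1:10000, function(s)
    project_landmarks(rbind(LM = c(0, 0, 0)), vw, noise_sd = 2,
                      seed = s)$u_px, numeric(1))
  expect_equal(sd(u), 2, tolerance = 0.05)
  ## deterministic given seed
  expect_identical(project_landmarks(rbind(LM = c(5, 1, 2)), vw, 1, seed = 9),
                   project_landmarks(rbind(LM = c(5, 1, 2)), vw, 1, seed = 9))
})

test_that("zero-noise multi-view reconstruction is exact", {
  views <- default_views(pixel_spacing = 0.4)
  mesh <- tpl_small()
  key <- c("AM_ANT", "AM_POST", "COMM_A", "COMM_P", "ANT_TIP", "P2_TIP")
  truth <- mesh$vertices[mesh$landmarks[key], ]
  rownames(truth) <- key
  obs <- do.call(rbind, lapply(views, function(vw)
    project_landmarks(truth, vw, noise_sd = 0)))
  rec <- reconstruct_landmarks(obs, views)
  expect_lt(max(abs(rec$points[key, ] - truth)), 1e-9)
  expect_lt(max(rec$residuals), 1e-9)
})

test_that("under-observed or degenerate view sets are rejected by name", {
  views <- default_views()
  one_view <- project_landmarks(rbind(APEX = c(1, 1, 1)), views[[1]], 0)
  expect_error(reconstruct_landmarks(one_view, views), "APEX.*fewer than 2")
  ## two parallel views cannot resolve depth
  v1 <- echo_view("a", c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  v2 <- echo_view("b", c(0, 0, 5), c(1, 0, 0), c(0, 1, 0))
  obs <- rbind(project_landmarks(rbind(LM = c(1, 2, 3)), v1, 0),
               project_landmarks(rbind(LM = c(1, 2, 3)), v2, 0))
  expect_error(reconstruct_landmarks(obs, list(v1, v2)), "LM.*parallel")
})

test_that("reconstruction RMSE matches the closed-form least-squares value", {
  ## 3 orthogonal views, spacing 0.5 mm/px, click noise 1 px: each world
  ## coordinate is measured in exactly 2 views, so the LS estimate averages
  ## two N(0, 0.5 mm) measurements; 3-D RMSE = sqrt(3 * 0.5^2 / 2).
  views <- default_views(pixel_spacing = 0.5)
  truth <- rbind(LM = c(3.1, -2.4, 5.7))
  set.seed(31)
  sq <- replicate(1000, {
    obs <- do.call(rbind, lapply(views, function(vw)
      project_landmarks(truth, vw, noise_sd = 1,
                        seed = sample.int(1e9, 1))))
    sum((reconstruct_landmarks(obs, views)$points[1, ] - truth)^2)
  })
  expect_equal(sqrt(mean(sq)), sqrt(3 * 0.5^2 / 2), tolerance = 0.05)
})

test_that("cohort generation is seeded, bounded, and consistent", {
  cohort <- generate_patient_cohort(29, seed = 7)
  expect_length(cohort, 29)
  expect_identical(cohort, generate_patient_cohort(29, seed = 7))
  expect_false(identical(cohort[[1]]$true, cohort[[2]]$true))
  b <- mv_parameter_bounds()
  for (rec in cohort) {
    tr <- unclass(rec$true)
    expect_true(all(tr >= b$lower & tr <= b$upper))
  }
  ## no variation, no noise: reconstruction returns the base valve
  c0 <- generate_patient_cohort(3, variation = 0, noise_sd = 0, seed = 2)
  for (rec in c0)
    expect_equal(unclass(rec$reconstructed),
                 unclass(mv_default_parameters()), tolerance = 1e-9)
})

test_that("parameter recovery error shrinks with digitization noise", {
  ## RMSE over the four directly triangulated parameters (the P1/P3 depths
  ## are inferred by scaling and carry a noise-independent floor)
  direct <- c("aml", "p2", "d_am", "d_ic")
  rmse <- function(noise) {
    cohort <- generate_patient_cohort(12, variation = 0.5, noise_sd = noise,
                                      seed = 42)
    sqrt(mean(vapply(cohort, function(r)
      mean((unclass(r$reconstructed)[direct] - unclass(r$true)[direct])^2),
      numeric(1))))
  }
  expect_lt(rmse(0.1), rmse(1) / 2)
})

test_that("pixel observation CSV round-trips", {
  vw <- default_views()[[1]]
  obs <- project_landmarks(rbind(A = c(1, 2, 3), B = c(-2, 0, 1)), vw,
                           noise_sd = 1, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(obs, path)
  expect_equal(read_observations_csv(path), obs, tolerance = 1e-12)
})
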
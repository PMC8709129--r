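test_that("percentile levels reproduce the bundled morphometry table", {
  ## sd back-derived from the printed 5th percentile of each depth
  rows <- list(aml = c(13.63, 20.6, 27.57), p1 = c(6.85, 11, 15.15),
               p2 = c(8.25, 12.9, 17.55), p3 = c(6.08, 10.4, 14.72))
  for (nm in names(rows)) {
    med <- rows[[nm]][2]
    sd <- (med - rows[[nm]][1]) / qnorm(0.95)
    got <- normal_percentiles(med, sd, c(0.05, 0.5, 0.95))
    expect_equal(round(got, 2), rows[[nm]])
  }
  expect_equal(normal_percentiles(12.3, 4, 0.5), 12.3)
})

test_that("percentiles agree with a bisection inversion of the normal CDF", {
  invert_cdf <- function(p, mean, sd) {   # independent oracle
    lo <- mean - 12 * sd; hi <- mean + 12 * sd
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pnorm(mid, mean, sd) < p) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (p in c(0.05, 0.2, 0.5, 0.8, 0.95))
    expect_equal(normal_percentiles(20.6, 4.24, p), invert_cdf(p, 20.6, 4.24),
                 tolerance = 1e-9)
  ## symmetric probabilities sit symmetrically about the mean
  v <- normal_percentiles(10, 2, c(0.05, 0.95))
  expect_equal(v[1] + v[2], 20, tolerance = 1e-12)
  expect_error(normal_percentiles(10, 2, 1.2), "inside")
  expect_error(normal_percentiles(10, -1, 0.5), "sd")
})

test_that("default plan enumerates 106 sets, 81 from the leaflet factorial", {
  sets <- enumerate_parameter_sets(default_literature_plan())
  expect_identical(nrow(sets), 106L)
  expect_identical(sum(sets$portion == "leaflet_factorial"), 81L)
  expect_identical(sum(sets$portion == "diameter_grid"), 25L)
  expect_false(anyDuplicated(sets$id) > 0)
  ## deterministic order
  expect_identical(sets, enumerate_parameter_sets(default_literature_plan()))
  ## full cross-portion dedupe removes the single coincident combination
  expect_identical(nrow(enumerate_parameter_sets(default_literature_plan(),
                                                 dedupe = "all")), 105L)
})

test_that("enumeration matches a brute-force nested-loop oracle", {
  plan <- enumeration_plan(
    leaflet_levels = list(aml = 14, p1 = 7, p2 = 8, p3 = 6),
    diameter_levels = list(d_am = c(21, 22, 23, 24, 25),
                           d_ic = c(17, 18, 19, 20, 21)),
    fixed_leaflet_values = c(aml = 14, p1 = 7, p2 = 8, p3 = 6)
  )
  ## oracle: build every combination by explicit loops
  oracle <- list()
  for (a in plan$leaflet_levels$aml) for (q1 in plan$leaflet_levels$p1)
    for (q2 in plan$leaflet_levels$p2) for (q3 in plan$leaflet_levels$p3)
      oracle[[length(oracle) + 1]] <- c(a, q1, q2, q3, 21, 17)
  for (da in plan$diameter_levels$d_am) for (di in plan$diameter_levels$d_ic)
    oracle[[length(oracle) + 1]] <- c(14, 7, 8, 6, da, di)
  sets <- enumerate_parameter_sets(plan)
  expect_identical(nrow(sets), length(oracle))            # 1 + 25 per portion
  got <- apply(sets[, c("aml", "p1", "p2", "p3", "d_am", "d_ic")], 1,
               paste, collapse = "|")
  want <- vapply(oracle, paste, "", collapse = "|")
  expect_setequal(got, want)
  ## collapsing portions drops the coincident (first-level) combination
  expect_identical(nrow(enumerate_parameter_sets(plan, dedupe = "all")), 25L)
})

test_that("literature atlas morphs hit every requested parameter set", {
  tpl <- tpl_small(resolution = 4)
  ## restricted plan keeps the check fast while spanning the extremes
  plan <- enumeration_plan(
    leaflet_levels = list(aml = c(13.63, 27.57), p1 = c(6.85, 15.15),
                          p2 = 8.25, p3 = 6.08),
    diameter_levels = list(d_am = c(21.5, 23.5), d_ic = c(17.65, 19.65)),
    fixed_leaflet_values = c(aml = 13.63, p1 = 6.85, p2 = 8.25, p3 = 6.08)
  )
  res <- build_literature_atlas(tpl, plan)
  expect_identical(nrow(res$manifest), 8L)     # 2*2*1*1 + 2*2
  expect_true(all(res$manifest$status == "ok"))
  expect_true(all(res$manifest$residual_mm < 0.1))
  ## measured-back values in the manifest are honest re-measurements
  m1 <- res$meshes[[res$manifest$id[1]]]
  expect_equal(measure_parameters(m1)[["aml"]], res$manifest$meas_aml[1])
})

test_that("bundled levels CSV matches the in-code table", {
  path <- system.file("extdata", "literature_levels.csv", package = "mvatlas")
  expect_true(nzchar(path))
  expect_equal(read.csv(path), literature_parameter_levels())
})
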
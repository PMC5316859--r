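test_that("monochromatic limit gives a cosine at the envelope frequency", {
  g <- default_grid()
  env <- laser_envelope("II", 1450, grid = g)
  i0 <- which.min(abs(g$values - 1400))
  env$values <- replace(rep(0, length(g$values)), i0, 1)  # single-bin source
  env$support <- env$values > 0
  d <- default_positions()
  ig <- simulate_interferogram(rep(1 + 0i, length(g$values)), env, d)
  expected <- g$resolution * cos(2 * pi * g$values[i0] * d)
  expect_equal(ig$values, expected, tolerance = 1e-12)
  sp <- spectrum_from_interferogram(ig)
  expect_equal(sp$grid$values[which.max(sp$amplitude)], g$values[i0])
})

test_that("path drift enters the spectrum as exp(i 2 pi nu delta)", {
  g <- default_grid()
  env <- laser_envelope("II", 1450, grid = g)
  comp <- component_library(g)$AC
  delta <- 1e-5                                     # 100 nm
  sp0 <- spectrum_from_interferogram(simulate_interferogram(comp, env))
  spd <- spectrum_from_interferogram(
    simulate_interferogram(comp, env, path_drift = delta))
  qm <- match(round(g$values / sp0$grid$resolution, 6),
              round(sp0$grid$values / sp0$grid$resolution, 6))
  dphi <- wrap_deg(spd$phase[qm] - sp0$phase[qm])[env$support]
  pred <- wrap_deg(phase_offset_from_path_drift(g$values[env$support], delta))
  expect_equal(dphi, pred, tolerance = 1e-6)
  # constant-offset approximation: spread bounded by the in-band ramp
  expect_lt(diff(range(dphi)), 360 * env$bandwidth * delta + 1e-9)
  expect_equal(mean(dphi), 360 * mean(g$values[env$support]) * delta,
               tolerance = 0.05)
})

test_that("I(0) equals the independent direct sum over the band", {
  g <- default_grid()
  env <- laser_envelope("II", 1450, grid = g)
  comp <- component_library(g)$FP
  ig <- simulate_interferogram(comp, env)
  # brute-force oracle at d = 0
  oracle <- 0
  for (j in seq_along(g$values))
    oracle <- oracle + Re(env$values[j] * comp$response[j]) * g$resolution
  expect_equal(ig$values[1], oracle, tolerance = 1e-12)
})

test_that("noiseless roundtrip recovers the component phase on the band support", {
  g <- default_grid()
  env <- laser_envelope("II", 1450, grid = g)
  comp <- component_library(g)$AC
  sp <- spectrum_from_interferogram(simulate_interferogram(comp, env))
  ref <- spectrum_from_interferogram(
    simulate_interferogram(rep(1 + 0i, length(g$values)), env))
  qm <- match(round(g$values / sp$grid$resolution, 6),
              round(sp$grid$values / sp$grid$resolution, 6))
  nrm <- normalize_line(sp$values[qm], ref$values[qm], support = env$support)
  err <- (nrm$phase[1, ] - comp$phase)[env$support]
  expect_lt(sqrt(mean(err^2)), 0.5)
  expect_lt(sqrt(mean(err^2)), 0.1)  # noise floor at pad_factor >= 4
})

test_that("Fourier reconstruction is linear", {
  g <- default_grid()
  env <- laser_envelope("I", 1170, grid = g)
  comps <- component_library(g)
  ig1 <- simulate_interferogram(comps$AC, env)
  ig2 <- simulate_interferogram(comps$FP, env)
  mix <- ig1; mix$values <- 2 * ig1$values - 0.5 * ig2$values
  s1 <- spectrum_from_interferogram(ig1)$values
  s2 <- spectrum_from_interferogram(ig2)$values
  sm <- spectrum_from_interferogram(mix)$values
  expect_equal(sm, 2 * s1 - 0.5 * s2, tolerance = 1e-12)
})

test_that("mirror travel of 1/35 cm reports 35 cm-1 nominal resolution", {
  g <- default_grid()
  env <- laser_envelope("II", 1450, grid = g)
  ig <- simulate_interferogram(rep(1 + 0i, length(g$values)), env,
                               positions = default_positions(128L, 1 / 4480))
  expect_equal(ig$meta$nominal_resolution_cm1, 35)
  sp <- spectrum_from_interferogram(ig)
  expect_equal(sp$meta$nominal_resolution_cm1, 35)
})

test_that("path-drift phase relation and its inverse match the stated figures", {
  # 100 nm drift at 1660 cm-1 -> about 6 degrees
  expect_equal(phase_offset_from_path_drift(1660, 1e-5), 5.976)
  expect_equal(round(phase_offset_from_path_drift(1660, 1e-5)), 6)
  expect_equal(phase_offset_from_path_drift(1234, 0), 0)
  # 1 degree at 1400 cm-1 -> about 20 nm stability requirement
  delta_nm <- path_drift_for_offset(1400, 1) * 1e7
  expect_equal(signif(delta_nm, 2), 20)
  expect_error(phase_offset_from_path_drift(-5, 1e-5), "nu")
})

test_that("interferometry input validation", {
  g <- default_grid()
  env <- laser_envelope("II", 1450, grid = g)
  expect_error(simulate_interferogram(rep(1 + 0i, 5), env), "grid")
  bad <- simulate_interferogram(rep(1 + 0i, length(g$values)), env)
  bad$positions <- bad$positions^1.01
  expect_error(spectrum_from_interferogram(bad), "uniform")
  short <- simulate_interferogram(rep(1 + 0i, length(g$values)), env,
                                  positions = default_positions(32L))
  expect_error(spectrum_from_interferogram(short), "64")
  # envelope support width matches the effective bandwidth within 10%
  sup <- range(g$values[env$support])
  expect_lt(abs(diff(sup) - env$bandwidth) / env$bandwidth, 0.1)
})
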
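test_that("stage-drift estimation recovers constructed shifts", {
  set.seed(42)
  img <- matrix(rnorm(40 * 50), 40, 50)
  img <- img + 3 * outer(sin(seq_len(40) / 4), cos(seq_len(50) / 5))
  expect_equal(estimate_stage_drift(img, img), c(dx = 0, dy = 0))
  # now[y, x] = ref[y + dy, x + dx] for (dx, dy) = (3, -2)
  shifted <- img[((seq_len(40) - 1 - 2) %% 40) + 1,
                 ((seq_len(50) - 1 + 3) %% 50) + 1]
  expect_equal(estimate_stage_drift(img, shifted), c(dx = 3, dy = -2))
  noisy <- shifted + rnorm(length(shifted), 0, sd(shifted) / 10)  # SNR 10
  est <- estimate_stage_drift(img, noisy)
  expect_lt(max(abs(est - c(3, -2))), 0.2)
  expect_error(estimate_stage_drift(matrix(1, 8, 8), matrix(1, 8, 8)),
               "flat")
  expect_error(estimate_stage_drift(img, img[1:20, ]), "equal shape")
})

test_that("line normalization identities hold", {
  g <- default_grid()
  ref <- (1 + 0.1 * sin(g$values / 100)) * exp(1i * g$values / 2000)
  self <- normalize_line(ref, ref)
  expect_equal(self$amplitude[1, ], rep(1, length(g$values)))
  expect_equal(self$phase[1, ], rep(0, length(g$values)))
  rot <- normalize_line(ref * exp(1i * pi / 6), ref)
  expect_equal(rot$phase[1, ], rep(30, length(g$values)), tolerance = 1e-12)
  expect_error(normalize_line(ref, ref * 0), "degenerate")
})

test_that("shared path drift cancels in normalization; sample-only drift survives", {
  g <- default_grid()
  env <- laser_envelope("II", 1450, grid = g)
  comp <- component_library(g)$AC
  delta <- 8e-6
  rec <- function(sigma, pd) {
    sp <- spectrum_from_interferogram(simulate_interferogram(sigma, env,
                                                             path_drift = pd))
    qm <- match(round(g$values / sp$grid$resolution, 6),
                round(sp$grid$values / sp$grid$resolution, 6))
    sp$values[qm]
  }
  si <- rep(1 + 0i, length(g$values))
  shared <- normalize_line(rec(comp$response, delta), rec(si, delta),
                           support = env$support)
  expect_equal(shared$phase[1, env$support], comp$phase[env$support],
               tolerance = 1e-6)
  only_sample <- normalize_line(rec(comp$response, delta), rec(si, 0),
                                support = env$support)
  offs <- (only_sample$phase[1, ] - comp$phase)[env$support]
  nu_bar <- mean(g$values[env$support])
  expect_equal(mean(offs), phase_offset_from_path_drift(nu_bar, delta),
               tolerance = 0.05)
})

test_that("acquisition time accounting matches direct arithmetic", {
  expect_equal(round(estimate_acquisition_time(5084, 1.66), 1), 2.3)
  expect_equal(estimate_acquisition_time(0, 1.66, 3, 600), 0.5)
  expect_equal(estimate_acquisition_time(0, 99), 0)
  # three cubes with 10 min overhead each: 7.53 h by direct arithmetic
  expect_equal(estimate_acquisition_time(5084, 1.66, 3, 600),
               3 * (5084 * 1.66 + 600) / 3600)
  # the published-style accounting: rounded per-cube time + 10 min, x3
  expect_equal(3 * (round(estimate_acquisition_time(5084, 1.66), 1) + 10 / 60),
               7.4)
})

test_that("noiseless drift-free scan reproduces the scene truth on the band support", {
  sc <- make_blend_scene(seed = 0)
  env <- laser_envelope("II", 1450, grid = sc$grid)
  plan <- scan_plan(c(10, 12), m = 2, reposition = FALSE)
  cube <- simulate_scan(sc, env, plan)
  err <- (cube$phase - sc$truth_phase[1:10, 1:12, , drop = FALSE])[, , env$support]
  expect_lt(sqrt(mean(err^2)), 0.5)
  # scan is deterministic: same seed, same cube
  c2 <- simulate_scan(sc, env, plan, noise_sd = 0.3, seed = 5)
  c3 <- simulate_scan(sc, env, plan, noise_sd = 0.3, seed = 5)
  expect_identical(c2$phase, c3$phase)
})

test_that("uncorrected linear drift shears the image by the predicted amount", {
  sc <- make_blend_scene(seed = 0)
  env <- laser_envelope("II", 1450, grid = sc$grid)
  ny <- 24L
  plan <- scan_plan(c(ny, 20), m = 2, reposition = FALSE, origin = c(20, 20))
  t_line <- (ny + 1) * plan$t_spectrum
  px_per_2lines <- 1
  dr <- drift_trajectory(rate = c(px_per_2lines * 30 / (2 * t_line), 0),
                         sine_amp = c(0, 0))
  cube <- simulate_scan(sc, env, plan, stage_drift = dr)
  # geometric oracle: pixel (iy, ix) is recorded at time
  # ((ix-1) * (ny+1) + 1 + iy) * t_spectrum and samples scene column
  # 19 + ix + round(drift_x(t) / 30)
  for (ix in c(5L, 15L)) {
    for (iy in c(3L, 18L)) {
      t_px <- ((ix - 1) * (ny + 1) + 1 + iy) * plan$t_spectrum
      pred_shift <- round(dr$offset(t_px)[1] / 30)
      truth <- sc$truth_phase[19 + iy, 19 + ix + pred_shift, env$support]
      expect_equal(cube$phase[iy, ix, env$support], truth, tolerance = 1e-9)
    }
  }
})

test_that("repositioning after each block bounds the residual displacement", {
  sc <- make_blend_scene(seed = 0)
  env <- laser_envelope("II", 1450, grid = sc$grid)
  plan <- scan_plan(c(24, 20), m = 2, reposition = TRUE, origin = c(20, 20))
  t_line <- 25 * plan$t_spectrum
  dr <- drift_trajectory(rate = c(30 / (2 * t_line), 0), sine_amp = c(0, 0))
  cube <- simulate_scan(sc, env, plan, stage_drift = dr, seed = 3)
  expect_gt(nrow(cube$drift_log), 0)
  expect_lte(max(abs(cube$drift_log$residual_dx_px)), 1)
  expect_lte(max(abs(cube$drift_log$residual_dy_px)), 1)
})

test_that("drift beyond the scene margin raises a boundary error", {
  sc <- make_blend_scene(seed = 0)
  env <- laser_envelope("II", 1450, grid = sc$grid)
  plan <- scan_plan(sc$shape, m = 2, reposition = FALSE)
  dr <- drift_trajectory(rate = c(2, 0), sine_amp = c(0, 0))  # 2 nm/s
  expect_error(simulate_scan(sc, env, plan, stage_drift = dr),
               "margin")
})
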
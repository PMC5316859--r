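test_that("phase offset estimation averages wrapped differences circularly", {
  g <- default_grid()
  nu <- g$values
  phi <- 5 * sin(nu / 120)
  ov <- 40:55
  expect_equal(estimate_phase_offset(phi, phi, ov), 0)
  expect_equal(estimate_phase_offset(phi, phi + 12, ov), 12, tolerance = 1e-9)
  # path-drift offsets: mean of 360 nu delta over the overlap (direct oracle)
  delta <- 1e-5
  shifted <- phi + 360 * nu * delta
  oracle <- mean(360 * nu[ov] * delta)
  expect_equal(estimate_phase_offset(phi, shifted, ov), oracle,
               tolerance = 1e-6)
  expect_error(estimate_phase_offset(phi, phi, 1:2), "3 grid points")
})

make_offset_cubes <- function(offsets = c(0, 0, 0), npx = c(3, 4)) {
  g <- default_grid()
  bands <- default_bands(g)
  truth <- 8 * exp(-((g$values - 1400) / 180)^2) +
    5 * exp(-((g$values - 1700) / 120)^2)
  cubes <- list()
  for (k in 1:3) {
    ph <- array(rep(truth + offsets[k], each = prod(npx)),
                c(npx, length(g$values)))
    cubes[[c("I", "II", "III")[k]]] <- structure(list(
      band_id = c("I", "II", "III")[k], grid = g, shape = npx, phase = ph,
      amplitude = ph * 0 + 1, support = bands[[k]]$support,
      envelope = bands[[k]], meta = list(center = bands[[k]]$center,
                                         pixel_size = 30),
      drift_log = data.frame()), class = "nf_band_cube")
  }
  list(cubes = cubes, truth = truth, grid = g)
}

test_that("constructed per-band offsets are recovered within 0.05 degrees", {
  mk <- make_offset_cubes(c(-8, 0, 5))
  corr <- correct_offsets(mk$cubes$I, mk$cubes$II, mk$cubes$III)
  expect_equal(max(abs(corr$offset_I - 8)), 0, tolerance = 0.05)
  expect_equal(max(abs(corr$offset_III + 5)), 0, tolerance = 0.05)
  ov <- overlap_indices(mk$cubes$I, mk$cubes$II)
  resid <- corr$cubes$I$phase[1, 1, ov] - corr$cubes$II$phase[1, 1, ov]
  expect_lt(max(abs(resid)), 0.1)
})

test_that("zero offsets pass through unchanged; near-180 offsets wrap correctly", {
  mk0 <- make_offset_cubes(c(0, 0, 0))
  corr0 <- correct_offsets(mk0$cubes$I, mk0$cubes$II, mk0$cubes$III)
  expect_equal(corr0$cubes$I$phase, mk0$cubes$I$phase, tolerance = 1e-12)
  mk <- make_offset_cubes(c(179, 0, 0))
  corr <- correct_offsets(mk$cubes$I, mk$cubes$II, mk$cubes$III)
  ov <- overlap_indices(mk$cubes$I, mk$cubes$II)
  resid <- corr$cubes$I$phase[2, 2, ov] - corr$cubes$II$phase[2, 2, ov]
  expect_lt(max(abs(wrap_deg(resid))), 0.1)
})

test_that("weights form a partition of unity with linear ramps", {
  g <- default_grid()
  bands <- default_bands(g)
  w <- build_weights(bands, g)
  expect_true(all(w$F >= 0 & w$F <= 1))
  expect_equal(colSums(w$F)[w$union], rep(1, sum(w$union)))
  for (k in 1:3) expect_true(all(w$F[k, !bands[[k]]$support] == 0))
  # exclusive support of band II carries full weight
  excl <- bands$II$support & !bands$I$support & !bands$III$support
  expect_true(all(w$F[2, excl] == 1))
  # linear ramp: F at the overlap midpoint interpolates to 0.5
  ov <- w$overlap_12
  mid <- mean(range(g$values[ov]))
  f1_mid <- stats::approx(g$values[ov], w$F[1, ov], xout = mid)$y
  expect_equal(f1_mid, 0.5, tolerance = 1e-12)
  # a frequency covered by all three supports is rejected
  s <- lapply(bands, function(b) b$support)
  s[[1]][which(s[[2]] & s[[3]])[1]] <- TRUE
  expect_error(build_weights(s, g), "unsupported")
})

test_that("stitching three restrictions of one spectrum reproduces it", {
  mk <- make_offset_cubes(c(0, 0, 0))
  w <- build_weights(mk$cubes, mk$grid)
  hyper <- stitch(mk$cubes, w)
  keep <- which(w$union)
  expect_equal(hyper$phase[2, 3, ], mk$truth[keep], tolerance = 1e-9)
})

test_that("baseline correction identities", {
  g <- default_grid()
  nu <- g$values
  anchors <- c(1030, 1870)
  ramp <- 3 + 0.01 * nu
  expect_equal(baseline_correct(ramp, anchors, g), rep(0, length(nu)),
               tolerance = 1e-12)
  expect_equal(baseline_correct(rep(7, length(nu)), anchors, g),
               rep(0, length(nu)), tolerance = 1e-12)
  lorentz <- 10 / (1 + ((nu - 1450) / 60)^2)
  spec <- lorentz + ramp
  out <- baseline_correct(spec, anchors, g)
  # peak height above the anchor line is preserved (analytic comparison)
  line <- function(v) {
    j <- function(w0) approx(nu, v, xout = w0)$y
    j(anchors[1]) + (j(anchors[2]) - j(anchors[1])) *
      (nu - anchors[1]) / diff(anchors)
  }
  expect_equal(max(out), max(spec - line(spec)), tolerance = 1e-9)
  # vanishes exactly at the anchors; idempotent
  expect_equal(approx(nu, out, xout = anchors)$y, c(0, 0), tolerance = 1e-12)
  expect_equal(baseline_correct(out, anchors, g), out, tolerance = 1e-12)
  expect_error(baseline_correct(spec, c(500, 1800), g), "outside")
  expect_error(baseline_correct(spec, c(1800, 1030), g), "w_b1")
})

test_that("a common constant passes through offsets and stitching, and baseline removes it", {
  mk <- make_offset_cubes(c(-4, 0, 3))
  shifted <- lapply(mk$cubes, function(cb) { cb$phase <- cb$phase + 25; cb })
  w <- build_weights(mk$cubes, mk$grid)
  h1 <- stitch(correct_offsets(mk$cubes$I, mk$cubes$II, mk$cubes$III), w)
  h2 <- stitch(correct_offsets(shifted$I, shifted$II, shifted$III), w)
  expect_equal(h2$phase, h1$phase + 25, tolerance = 1e-9)
  b1 <- baseline_correct(h1); b2 <- baseline_correct(h2)
  expect_equal(b1$phase, b2$phase, tolerance = 1e-9)
})

test_that("noiseless end-to-end pipeline recovers the truth cube", {
  res <- noiseless_run()
  expect_lt(truth_rms(res), 0.7)
  # overlap continuity: stitched minus truth jumps stay below 0.2 degrees
  hyper <- res$hypercube
  idx_h <- which(hyper$grid$values >= 1030 & hyper$grid$values <= 1870)
  idx_s <- match(round(hyper$grid$values[idx_h], 6),
                 round(res$scene$grid$values, 6))
  err <- hyper$phase[3, 4, idx_h] -
    truth_baselined(res$scene)[3, 4, idx_s]
  expect_lt(max(abs(diff(err))), 0.2)
})

test_that("recovered offset maps follow the analytic path-drift relation", {
  res <- default_run()
  g <- res$scene$grid$values
  ov <- overlap_indices(res$band_cubes$I, res$band_cubes$II)
  nu_bar <- mean(g[ov])
  # per-line injected drifts differ between bands I and II; the recovered
  # offset is band II's minus band I's drift phase at the overlap centre
  d_I <- res$band_cubes$I$interferometer_drift
  d_II <- res$band_cubes$II$interferometer_drift
  pred <- phase_offset_from_path_drift(nu_bar, d_II - d_I)  # per line
  est_by_line <- colMeans(res$corrected$offset_I)
  ramp_bound <- 360 * 350 * max(abs(d_II - d_I))
  expect_lt(max(abs(est_by_line - pred)), ramp_bound + 0.6)
  # the line-to-line offset variations track the injected drift walk
  expect_gt(stats::cor(est_by_line, pred), 0.5)
})
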
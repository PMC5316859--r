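toy_grid <- function(n = 3) frequency_grid(seq(1000, by = 100, length.out = n))

test_that("euclidean distance maps match hand computations and invariances", {
  g <- toy_grid(3)
  ph <- array(0, c(1, 2, 3))
  ph[1, 2, ] <- c(3, 4, 0)
  cube <- make_toy_cube(ph, g)
  dm <- euclidean_distance_map(cube, c(0, 0, 0))
  expect_equal(dm$values[1, 1], 0)
  expect_equal(dm$values[1, 2], 5)
  # invariant under adding a constant to both cube and reference
  cube2 <- make_toy_cube(ph + 11, g)
  dm2 <- euclidean_distance_map(cube2, c(11, 11, 11))
  expect_equal(dm2$values, dm$values)
  expect_error(euclidean_distance_map(cube, c(0, 0, 0), range = c(1, 2)),
               "empty")
})

test_that("composite maps encode distance as colour intensity", {
  g <- toy_grid(3)
  mk_map <- function(vals) structure(list(values = vals, range = c(1000, 1200),
                                          reference_name = "x"),
                                     class = "nf_distmap")
  v <- matrix(c(0, 10, 10, 5), 2, 2)
  w <- matrix(c(10, 10, 0, 5), 2, 2)
  cm <- composite_map(list(mk_map(v), mk_map(w)), c("red", "blue"),
                      clip = c(0, 1))
  expect_equal(cm$values[1, 1, ], c(1, 0, 0))   # close to red ref only
  expect_equal(cm$values[1, 2, ], c(0, 0, 1))   # close to blue ref only
  expect_equal(cm$values[2, 1, ], c(0, 0, 0))   # far from both: black
  expect_equal(cm$values[2, 2, 1], cm$values[2, 2, 3])  # purple balance
  expect_gt(cm$values[2, 2, 1], 0)
  expect_error(composite_map(list(mk_map(v), mk_map(w[1, , drop = FALSE]))),
               "shape")
})

test_that("d_value matches the Pearson definition and its bounds", {
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  expect_equal(d_value(a, a), 0)
  expect_equal(d_value(a, -a), 2000)
  # independent brute-force Pearson evaluation
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(d_value(a, b), (1 - r) * 1000)
  expect_equal(d_value(a, b), d_value(b, a))
  # affine invariance
  expect_equal(d_value(5 * a + 2, b), d_value(a, b))
  expect_error(d_value(a, c(1, 1, 1)), "variance")
  expect_error(d_value(a[1:2], b[1:2]), "3 points")
})

test_that("hca separates two noiseless populations perfectly", {
  g <- default_grid()
  comps <- component_library(g)
  ph <- array(0, c(6, 6, length(g$values)))
  truth <- matrix(1L, 6, 6); truth[, 4:6] <- 2L
  for (y in 1:6) for (x in 1:6)
    ph[y, x, ] <- if (truth[y, x] == 1) comps$keratin$phase else
      comps$melanin$phase
  cube <- make_toy_cube(ph, g)
  cl <- hca(cube, 2)
  expect_equal(adjusted_rand_index(truth, cl$labels), 1)
  expect_true(all(diff(cl$heights) >= -1e-9))   # Ward heights monotone
  expect_equal(sort(unique(as.integer(cl$labels))), 1:2)
  # labels renumbered by descending size
  expect_gte(cl$sizes[1], cl$sizes[2])
  one <- hca(cube, 1)
  expect_true(all(one$labels == 1L))
  expect_error(hca(cube, 100), "between 1 and")
})

test_that("cluster statistics are per-frequency means and population sds", {
  g <- toy_grid(3)
  ph <- array(0, c(2, 1, 3))
  ph[1, 1, ] <- c(0, 0, 0); ph[2, 1, ] <- c(10, 10, 10)
  cube <- make_toy_cube(ph, g)
  st <- cluster_stats(cube, matrix(c(1L, 1L), 2, 1))
  expect_equal(st$mean[1, ], c(5, 5, 5))
  expect_equal(st$sd[1, ], c(5, 5, 5))
  st2 <- cluster_stats(cube, matrix(c(1L, 2L), 2, 1))
  expect_equal(st2$sd[1, ], c(0, 0, 0))  # single-pixel cluster
  expect_equal(st2$mean[2, ], c(10, 10, 10))
})

test_that("unmixing recovers exact mixtures and flags non-superposable spectra", {
  g <- default_grid()
  comps <- component_library(g)
  refs <- list(FP = comps$FP, AC = comps$AC)
  u1 <- unmix(comps$FP$phase, refs)
  expect_equal(unname(u1$coefficients), c(1, 0), tolerance = 1e-8)
  expect_lt(u1$residual_rms, 1e-8)
  mix <- 0.3 * comps$FP$phase + 0.7 * comps$AC$phase
  u2 <- unmix(mix, refs)
  expect_equal(unname(u2$coefficients), c(0.3, 0.7), tolerance = 1e-6)
  # non-negativity binds for an anti-correlated target
  u3 <- unmix(-comps$FP$phase, list(FP = comps$FP), allow_offset = FALSE)
  expect_equal(unname(u3$coefficients), 0)
  # the interaction fixture is not a superposition of the pure references
  ui <- unmix(comps$interaction$phase, refs)
  expect_gt(ui$residual_rms, 1)
  expect_warning(unmix(mix, list(a = comps$FP, b = comps$FP)), "collinear")
})

test_that("superposition_test separates mixtures from the interaction fixture", {
  g <- default_grid()
  comps <- component_library(g)
  refs <- list(FP = comps$FP, AC = comps$AC)
  set.seed(7)
  mixes <- t(vapply(runif(12, 0.2, 0.8), function(w)
    w * comps$FP$phase + (1 - w) * comps$AC$phase +
      rnorm(length(g$values), 0, 0.2),
    numeric(length(g$values))))
  thr <- superposition_threshold(mixes, refs)
  pure <- superposition_test(comps$AC$phase, refs, thr)
  expect_true(pure$superposition)
  expect_lt(pure$unmix$residual_rms, 1e-8)
  expect_true(superposition_test(mixes[1, ], refs, thr)$superposition)
  expect_false(superposition_test(comps$interaction$phase, refs,
                                  thr)$superposition)
})

test_that("adjusted Rand index behaves as a chance-corrected agreement", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(2, 2, 3, 3, 1, 1)), 1)  # relabeling
  expect_lt(adjusted_rand_index(c(1, 1, 1, 2, 2, 2), c(1, 2, 1, 2, 1, 2)), 0.1)
})
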
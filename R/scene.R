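#' @section Synthetic scenes:
#' Scenes are stated worlds for testing the acquisition, stitching and
#' multivariate analysis machinery: a label map assigns each pixel a
#' composition rule (pure component, convex combination of components, or a
#' distinct "interaction" component), and ground-truth phase/amplitude cubes
#' are built from the rules. Mixing rules are defined as convex combinations
#' of the components' normalized PHASE spectra (not of their complex
#' responses), which makes linear-superposition testing exact by
#' construction; the per-pixel complex response used by the interferometer
#' simulation is then `amplitude * exp(i * phase)` with the amplitude mixed
#' the same way.
#' @name nanoftir-scenes
NULL

# ---- geometry helpers (row = y, col = x) -------------------------------

ellipse_mask <- function(shape, cy, cx, a, b, angle) {
  ny <- shape[1]; nx <- shape[2]
  yy <- matrix(seq_len(ny), ny, nx) - cy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  u <- cos(angle) * xx + sin(angle) * yy
  v <- -sin(angle) * xx + cos(angle) * yy
  (u / a)^2 + (v / b)^2 <= 1
}

disk_mask <- function(shape, cy, cx, radius) {
  ellipse_mask(shape, cy, cx, radius, radius, 0)
}

# pixels within Euclidean distance <= width of `mask` but outside it
ring_mask <- function(mask, width = 2) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  offs <- expand.grid(dy = -width:width, dx = -width:width)
  offs <- offs[offs$dy^2 + offs$dx^2 <= width^2, ]
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    y <- idx[, 1] + offs$dy[k]; x <- idx[, 2] + offs$dx[k]
    ok <- y >= 1 & y <= ny & x >= 1 & x <= nx
    out[cbind(y[ok], x[ok])] <- TRUE
  }
  out & !mask
}

# ---- scene assembly -----------------------------------------------------

# compositions: named list, each element list(type, components, weights)
# type: "pure" | "mix" | "interaction"
build_scene <- function(shape, pixel_size, grid, labels, label_names,
                        compositions, components, heights, seed) {
  ny <- shape[1]; nx <- shape[2]
  stopifnot(all(dim(labels) == shape), length(label_names) >= max(labels))
  if (any(labels < 1L)) stop("unlabeled pixels in scene", call. = FALSE)
  nlab <- length(label_names)
  nfreq <- length(grid$values)
  phase_by_label <- matrix(0, nlab, nfreq)
  amp_by_label <- matrix(1, nlab, nfreq)
  for (l in seq_len(nlab)) {
    rule <- compositions[[label_names[l]]]
    cw <- rule$weights
    if (rule$type != "pure" &&
        (any(cw < 0) || abs(sum(cw) - 1) > 1e-12))
      stop("mixing weights must be >= 0 and sum to 1", call. = FALSE)
    ph <- 0; am <- 0
    for (j in seq_along(rule$components)) {
      comp <- components[[rule$components[j]]]
      wj <- if (rule$type == "pure") 1 else cw[j]
      ph <- ph + wj * comp$phase
      am <- am + wj * comp$amplitude
    }
    phase_by_label[l, ] <- ph
    amp_by_label[l, ] <- am
  }
  truth_phase <- array(phase_by_label[labels, ], dim = c(ny, nx, nfreq))
  truth_amplitude <- array(amp_by_label[labels, ], dim = c(ny, nx, nfreq))
  height <- matrix(heights[labels], ny, nx)
  structure(list(shape = shape, pixel_size = pixel_size, grid = grid,
                 labels = labels, label_names = label_names,
                 compositions = compositions, components = components,
                 phase_by_label = phase_by_label,
                 amplitude_by_label = amp_by_label,
                 truth_phase = truth_phase,
                 truth_amplitude = truth_amplitude,
                 height = height, seed = seed),
            class = "nf_scene")
}

#' @export
print.nf_scene <- function(x, ...) {
  cat(sprintf("<nf_scene> %d x %d px (%.0f nm/px), %d labels: %s\n",
              x$shape[1], x$shape[2], x$pixel_size,
              length(x$label_names), paste(x$label_names, collapse = ", ")))
  invisible(x)
}

#' Synthetic three-component polymer blend scene
#'
#' Emulates a spin-coated blend of an acrylic copolymer (AC), a fluorine
#' copolymer (FP) and polystyrene (PS) on silicon: an AC background layer,
#' elliptical FP clusters probed as vertical FP+AC mixtures, PS disks, and
#' two kinds of cluster rims - "interaction" rims carrying a chemically
#' modified FP component (CF2 band shifted 1195 -> 1155 cm^-1, enhanced
#' 1155, reduced 1740 contribution) that is NOT a linear superposition of
#' the pure references, and "interface" rims that are plain lateral AC/FP
#' mixtures. Labels: 1 AC, 2 FP+AC cluster, 3 PS, 4 interaction, 5
#' interface.
#'
#' @param shape `c(ny, nx)` pixels, each >= 8; default `c(62, 82)`.
#' @param pixel_size Pixel size in nm (default 30).
#' @param seed Integer seed; scenes are bit-reproducible given the seed.
#' @param grid Frequency grid (default [default_grid()]).
#' @return An `nf_scene` (see package docs) with ground-truth label map and
#'   phase/amplitude cubes.
#' @export
make_blend_scene <- function(shape = c(62, 82), pixel_size = 30, seed = 0,
                             grid = default_grid()) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 8L))
    stop("shape must be at least (8, 8)", call. = FALSE)
  set.seed(seed)
  ny <- shape[1]; nx <- shape[2]
  comps <- component_library(grid)
  labels <- matrix(1L, ny, nx)        # AC background

  n_fp <- max(2L, round(ny * nx / 850))
  n_ps <- max(1L, round(ny * nx / 1700))
  # geometry scales down for small scenes; unchanged for the default size
  margin <- min(6L, max(3L, min(shape) %/% 5L))
  a_hi <- min(7, (nx - 2 * margin) / 4, (ny - 2 * margin) / 3)
  a_lo <- min(3.5, a_hi - 1)
  b_hi <- min(5.5, 0.8 * a_hi); b_lo <- min(2.5, b_hi - 0.5)
  r_hi <- min(4.5, a_hi); r_lo <- min(2.5, r_hi - 1)
  if (ny <= 2 * margin + 2 || nx <= 2 * margin + 2 || a_lo < 1.5)
    stop("shape too small to place all region types", call. = FALSE)

  fp_masks <- vector("list", n_fp)
  occupied <- matrix(FALSE, ny, nx)   # ellipses + exclusion rings
  solid <- matrix(FALSE, ny, nx)      # ellipses + PS disks only
  for (i in seq_len(n_fp)) {
    placed <- FALSE
    for (try in 1:120) {
      shrink <- 0.98^(try - 1)        # relax gradually on crowded scenes
      cy <- stats::runif(1, margin + 1, ny - margin)
      cx <- stats::runif(1, margin + 1, nx - margin)
      a <- max(1.8, stats::runif(1, a_lo, a_hi) * shrink)
      b <- max(1.5, stats::runif(1, b_lo, b_hi) * shrink)
      ang <- stats::runif(1, 0, pi)
      m <- ellipse_mask(shape, cy, cx, a, b, ang)
      if (!any(m & occupied)) { placed <- TRUE; break }
    }
    if (!placed) stop("shape too small to place all region types", call. = FALSE)
    fp_masks[[i]] <- m
    occupied <- occupied | ring_mask(m, 3) | m
    solid <- solid | m
  }
  ps_masks <- vector("list", n_ps)
  for (i in seq_len(n_ps)) {
    placed <- FALSE
    for (try in 1:120) {
      shrink <- 0.98^(try - 1)
      cy <- stats::runif(1, margin, ny - margin + 1)
      cx <- stats::runif(1, margin, nx - margin + 1)
      r <- max(1.5, stats::runif(1, r_lo, r_hi) * shrink)
      m <- disk_mask(shape, cy, cx, r)
      if (!any(m & solid)) { placed <- TRUE; break }
    }
    if (!placed) stop("shape too small to place all region types", call. = FALSE)
    ps_masks[[i]] <- m
    solid <- solid | m
  }

  # first half of the FP clusters get interaction rims, the rest interfaces
  n_int <- ceiling(n_fp / 2)
  for (i in seq_len(n_fp)) {
    rim <- ring_mask(fp_masks[[i]], 2)
    labels[rim] <- if (i <= n_int) 4L else 5L
    labels[fp_masks[[i]]] <- 2L
  }
  for (m in ps_masks) labels[m] <- 3L

  w_fp <- stats::runif(1, 0.70, 0.85)   # vertical FP share inside clusters
  w_if <- stats::runif(1, 0.35, 0.55)   # lateral FP share at interfaces
  label_names <- c("AC", "FP+AC", "PS", "interaction", "interface")
  compositions <- list(
    AC = list(type = "pure", components = "AC", weights = 1),
    `FP+AC` = list(type = "mix", components = c("FP", "AC"),
                   weights = c(w_fp, 1 - w_fp)),
    PS = list(type = "pure", components = "PS", weights = 1),
    interaction = list(type = "interaction", components = "interaction",
                       weights = 1),
    interface = list(type = "mix", components = c("FP", "AC"),
                     weights = c(w_if, 1 - w_if))
  )
  if (length(unique(as.integer(labels))) < 5L)
    stop("shape too small to place all region types", call. = FALSE)
  heights <- c(0, 60, 40, 55, 50)       # nm, for topography rendering
  build_scene(shape, pixel_size, grid, labels, label_names, compositions,
              comps[c("AC", "FP", "PS", "interaction")], heights, seed)
}

#' Synthetic hair cross-section scene
#'
#' Emulates a resin-embedded hair cross-section: featureless epoxy resin,
#' keratin-rich cortex (amide I/II bands), one surface melanin granule of
#' about 300 nm diameter with a 2-px keratin+melanin rim, and one
#' disk-shaped subsurface granule of about 200 nm diameter probed as a
#' 50/50 keratin+melanin mixture. Labels: 1 resin, 2 keratin (cortex),
#' 3 melanin, 4 melanin+keratin mixture (rim and subsurface).
#'
#' @inheritParams make_blend_scene
#' @param shape Default `c(64, 64)`.
#' @param pixel_size Default 25 nm.
#' @return An `nf_scene`.
#' @export
make_hair_scene <- function(shape = c(64, 64), pixel_size = 25, seed = 0,
                            grid = default_grid()) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 8L))
    stop("shape must be at least (8, 8)", call. = FALSE)
  set.seed(seed)
  ny <- shape[1]; nx <- shape[2]
  comps <- component_library(grid)
  labels <- matrix(2L, ny, nx)                       # cortex / keratin
  resin_cols <- seq_len(max(2L, round(nx * 0.18)))   # embedding resin strip
  labels[, resin_cols] <- 1L

  d_big <- round(300 / pixel_size)    # granule diameters in pixels
  d_sub <- round(200 / pixel_size)
  if (ny < d_big + 8 || nx < d_big + 8)
    stop("shape too small to place all region types", call. = FALSE)
  cortex_x0 <- max(resin_cols) + d_big
  cy1 <- ny * stats::runif(1, 0.3, 0.5)
  cx1 <- stats::runif(1, cortex_x0, nx - d_big / 2 - 4)
  big <- disk_mask(shape, cy1, cx1, d_big / 2)
  rim <- ring_mask(big, 2)
  cy2 <- ny * stats::runif(1, 0.65, 0.8)
  cx2 <- stats::runif(1, cortex_x0, nx - d_sub / 2 - 4)
  sub <- disk_mask(shape, cy2, cx2, d_sub / 2)
  labels[rim] <- 4L
  labels[big] <- 3L
  labels[sub & !big & !rim] <- 4L

  w <- 0.5
  label_names <- c("resin", "keratin", "melanin", "melanin+keratin")
  compositions <- list(
    resin = list(type = "pure", components = "resin", weights = 1),
    keratin = list(type = "pure", components = "keratin", weights = 1),
    melanin = list(type = "pure", components = "melanin", weights = 1),
    `melanin+keratin` = list(type = "mix",
                             components = c("melanin", "keratin"),
                             weights = c(w, 1 - w))
  )
  heights <- c(0, 30, 80, 60)
  build_scene(shape, pixel_size, grid, labels, label_names, compositions,
              comps[c("resin", "keratin", "melanin")], heights, seed)
}

# per-pixel complex response of a set of scene pixels (matrix npx x nfreq)
scene_sigma <- function(scene, iy, ix) {
  l <- scene$labels[cbind(iy, ix)]
  amp <- scene$amplitude_by_label[l, , drop = FALSE]
  ph <- deg2rad(scene$phase_by_label[l, , drop = FALSE])
  amp * exp(1i * ph)
}

# topography rendering for drift registration: height map sampled at an
# (integer-rounded) stage offset given in pixels, plus roughness noise
render_topography <- function(scene, offset_px = c(0, 0), noise_sd = 2,
                              window = NULL) {
  ny <- scene$shape[1]; nx <- scene$shape[2]
  if (is.null(window)) window <- c(ny, nx)
  iy <- clamp_idx(round(seq_len(window[1]) + offset_px[2]), ny)
  ix <- clamp_idx(round(seq_len(window[2]) + offset_px[1]), nx)
  scene$height[iy, ix, drop = FALSE] +
    matrix(stats::rnorm(window[1] * window[2], 0, noise_sd),
           window[1], window[2])
}

clamp_idx <- function(i, n, overhang = 2L) {
  if (any(i < 1L - overhang) || any(i > n + overhang))
    stop("stage drift exceeds scene margin (boundary error)", call. = FALSE)
  pmin(pmax(i, 1L), n)
}
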
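#' Overlap region of two band supports
#'
#' Grid indices where both band supports hold.
#'
#' @param a,b `nf_band_cube`s, `nf_envelope`s or logical support vectors on
#'   a common grid.
#' @return Integer vector of grid indices (error if empty).
#' @export
overlap_indices <- function(a, b) {
  sup <- function(x) {
    if (inherits(x, "nf_band_cube")) x$support
    else if (inherits(x, "nf_envelope")) x$support
    else as.logical(x)
  }
  idx <- which(sup(a) & sup(b))
  if (length(idx) == 0L)
    stop("empty spectral overlap between bands", call. = FALSE)
  idx
}

#' Constant phase offset between two spectra in an overlap region
#'
#' Circular mean of the wrapped phase differences `phi_b - phi_a` over the
#' overlap interval, returned in (-180, 180]. Circular averaging makes the
#' estimate robust for offsets near +-180 degrees.
#'
#' @param phi_a,phi_b Phase spectra in degrees on a common grid.
#' @param overlap Integer indices of the overlap region (>= 3 points).
#' @return Offset in degrees.
#' @export
estimate_phase_offset <- function(phi_a, phi_b, overlap) {
  if (length(overlap) < 3L)
    stop("overlap must contain at least 3 grid points", call. = FALSE)
  d <- deg2rad(phi_b[overlap] - phi_a[overlap])
  rad2deg(Arg(mean(exp(1i * d))))
}

#' Per-pixel offset correction of three band cubes
#'
#' Shifts the phase spectra of bands I and III at each pixel by the constant
#' offsets estimated in the (I,II) and (II,III) overlap regions so that they
#' match band II; band II is unchanged. Offsets are estimated by circular
#' averaging of the wrapped differences (see [estimate_phase_offset()]).
#'
#' @param cube_I,cube_II,cube_III `nf_band_cube`s on a shared pixel and
#'   frequency grid.
#' @return List with `cubes` (list `I`, `II`, `III` of corrected cubes) and
#'   the per-pixel offset maps `offset_I`, `offset_III` (degrees).
#' @export
correct_offsets <- function(cube_I, cube_II, cube_III) {
  stopifnot(all(cube_I$shape == cube_II$shape),
            all(cube_III$shape == cube_II$shape))
  if (max(abs(cube_I$grid$values - cube_II$grid$values)) > 1e-9 ||
      max(abs(cube_III$grid$values - cube_II$grid$values)) > 1e-9)
    stop("band cubes must share the frequency grid", call. = FALSE)
  ov12 <- overlap_indices(cube_I, cube_II)
  ov23 <- overlap_indices(cube_II, cube_III)
  pixel_offset <- function(cube_lo, cube_hi, ov) {
    # circular mean over the overlap, vectorized over pixels
    d <- deg2rad(cube_hi$phase[, , ov, drop = FALSE] -
                 cube_lo$phase[, , ov, drop = FALSE])
    z <- rowMeans(exp(1i * d), dims = 2L)
    rad2deg(Arg(z))
  }
  off_I <- pixel_offset(cube_I, cube_II, ov12)
  off_III <- pixel_offset(cube_III, cube_II, ov23)
  shift_cube <- function(cube, off) {
    cube$phase <- cube$phase + array(off, dim(cube$phase))
    cube
  }
  list(cubes = list(I = shift_cube(cube_I, off_I), II = cube_II,
                    III = shift_cube(cube_III, off_III)),
       offset_I = off_I, offset_III = off_III)
}

#' Stitching weight functions
#'
#' Builds the weight functions F^k on the common grid: 1 on each band's
#' exclusive support, a linear ramp in wavenumber across each pairwise
#' overlap, 0 outside the band support. The weights form a partition of
#' unity on the union of the supports. A frequency covered by all three
#' supports is rejected as an unsupported configuration.
#'
#' @param supports List of three logical support vectors (or
#'   `nf_envelope`s / `nf_band_cube`s) ordered by band centre.
#' @param grid Frequency grid shared by the supports.
#' @return Object of class `nf_weights`: matrix `F` (3 x nfreq, rows I, II,
#'   III), logical `union`, and the overlap index sets.
#' @export
build_weights <- function(supports, grid) {
  sup <- lapply(supports, function(x) {
    if (inherits(x, "nf_band_cube") || inherits(x, "nf_envelope")) x$support
    else as.logical(x)
  })
  stopifnot(length(sup) == 3L)
  if (!inherits(grid, "nf_grid")) grid <- frequency_grid(grid)
  w <- grid$values
  if (any(sup[[1]] & sup[[2]] & sup[[3]]))
    stop("all three band supports overlap at one frequency: unsupported ",
         "configuration", call. = FALSE)
  ctr <- vapply(sup, function(s) mean(w[s]), numeric(1))
  if (is.unsorted(ctr))
    stop("supports must be ordered by band centre", call. = FALSE)
  FF <- matrix(0, 3L, length(w))
  for (k in 1:3) FF[k, sup[[k]]] <- 1
  ramp <- function(lo_band, hi_band) {
    idx <- which(sup[[lo_band]] & sup[[hi_band]])
    if (length(idx) == 0L)
      stop("empty spectral overlap between bands", call. = FALSE)
    wl <- w[idx[1]]; wh <- w[idx[length(idx)]]
    tt <- if (wh > wl) (w[idx] - wl) / (wh - wl) else rep(0.5, length(idx))
    FF[lo_band, idx] <<- 1 - tt
    FF[hi_band, idx] <<- tt
    idx
  }
  ov12 <- ramp(1L, 2L)
  ov23 <- ramp(2L, 3L)
  union <- sup[[1]] | sup[[2]] | sup[[3]]
  stopifnot(max(abs(colSums(FF)[union] - 1)) < 1e-12)
  structure(list(F = FF, union = union, grid = grid,
                 overlap_12 = ov12, overlap_23 = ov23),
            class = "nf_weights")
}

#' Stitch offset-corrected band cubes into a broadband hypercube
#'
#' Sums the weighted phase spectra, `phi = sum_k F^k(w) phi^k(w)`, at every
#' pixel and crops the grid to the union of the band supports.
#'
#' @param corrected Result of [correct_offsets()], or a plain list of three
#'   corrected `nf_band_cube`s.
#' @param weights An [build_weights()] result; default built from the three
#'   cubes' supports.
#' @return Object of class `nf_hypercube`: `grid` (cropped), `phase`
#'   `[ny, nx, nfreq]` in degrees, `shape`, `pixel_size`, `provenance`
#'   (offset maps, weights, band metadata, baseline anchors once applied).
#' @export
stitch <- function(corrected, weights = NULL) {
  cubes <- if (!is.null(corrected$cubes)) corrected$cubes else corrected
  stopifnot(length(cubes) == 3L)
  g <- cubes[[2]]$grid
  for (cb in cubes)
    if (max(abs(cb$grid$values - g$values)) > 1e-9)
      stop("band cubes must share the frequency grid", call. = FALSE)
  if (is.null(weights)) weights <- build_weights(cubes, g)
  keep <- which(weights$union)
  ny <- cubes[[1]]$shape[1]; nx <- cubes[[1]]$shape[2]
  phase <- array(0, c(ny, nx, length(keep)))
  for (k in 1:3) {
    fk <- weights$F[k, keep]
    nz <- which(fk != 0)
    if (length(nz))
      phase[, , nz] <- phase[, , nz] +
        sweep(cubes[[k]]$phase[, , keep[nz], drop = FALSE], 3L, fk[nz], `*`)
  }
  structure(list(
    grid = frequency_grid(g$values[keep]), phase = phase,
    shape = c(ny, nx), pixel_size = cubes[[1]]$meta$pixel_size,
    provenance = list(
      offset_I = corrected$offset_I, offset_III = corrected$offset_III,
      weights = weights,
      bands = lapply(cubes, function(cb) cb$meta),
      baseline = NULL)),
    class = "nf_hypercube")
}

#' @export
print.nf_hypercube <- function(x, ...) {
  cat(sprintf("<nf_hypercube> %d x %d px, %.4g - %.4g cm-1 (%d points)%s\n",
              x$shape[1], x$shape[2], min(x$grid$values), max(x$grid$values),
              length(x$grid$values),
              if (is.null(x$provenance$baseline)) "" else ", baseline-corrected"))
  invisible(x)
}

#' Two-anchor linear baseline correction
#'
#' Subtracts from each phase spectrum the straight line through its values
#' at the two anchor frequencies (read by linear interpolation), assumed
#' absorption-free. The corrected spectrum vanishes exactly at both anchors
#' and the operation is idempotent.
#'
#' @param x An `nf_hypercube`, a phase matrix (pixels x frequencies), or a
#'   numeric phase spectrum.
#' @param anchors `c(w_b1, w_b2)` in cm^-1, inside the spectral range;
#'   default `c(1030, 1870)` - just inside the stitched range and away from
#'   the fixture peaks.
#' @param grid Frequency grid (taken from the cube when `x` is one).
#' @return Same type as `x`, baseline-corrected.
#' @export
baseline_correct <- function(x, anchors = c(1030, 1870), grid = NULL) {
  if (inherits(x, "nf_hypercube")) {
    g <- x$grid$values
    ph <- x$phase
    dm <- dim(ph)
    flat <- matrix(ph, prod(dm[1:2]), dm[3])
    out <- baseline_correct_matrix(flat, g, anchors)
    x$phase <- array(out, dm)
    x$provenance$baseline <- anchors
    return(x)
  }
  g <- grid_values(if (is.null(grid)) stop("grid required", call. = FALSE)
                   else grid)
  if (is.null(dim(x)))
    baseline_correct_matrix(matrix(x, 1L), g, anchors)[1L, ]
  else
    baseline_correct_matrix(x, g, anchors)
}

baseline_correct_matrix <- function(M, g, anchors) {
  stopifnot(length(anchors) == 2L)
  if (anchors[1] >= anchors[2])
    stop("anchors must satisfy w_b1 < w_b2", call. = FALSE)
  if (anchors[1] < g[1] || anchors[2] > g[length(g)])
    stop("baseline anchors outside spectral range", call. = FALSE)
  interp_at <- function(w0) {
    j <- findInterval(w0, g, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(g) - 1L)
    t0 <- (w0 - g[j]) / (g[j + 1] - g[j])
    (1 - t0) * M[, j] + t0 * M[, j + 1]
  }
  v1 <- interp_at(anchors[1])
  v2 <- interp_at(anchors[2])
  slope <- (v2 - v1) / (anchors[2] - anchors[1])
  M - outer(v1, rep(1, length(g))) - outer(slope, g - anchors[1])
}
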
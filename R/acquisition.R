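#' Raster scan plan
#'
#' Geometry and protocol of one band acquisition. Line scans are parallel to
#' the y axis: a line is one image column, pixels within a line are fast
#' (top to bottom), lines are slow (left to right). Before each line a
#' reference spectrum is recorded on a clean silicon area adjacent to the
#' imaged region, and when `reposition` is on the scan pauses after each
#' block of `m` lines to record a topography image, measure the accumulated
#' stage drift against the initial topography and reposition the scanner.
#'
#' @param shape `c(ny, nx)` scan window in pixels.
#' @param pixel_size Pixel size in nm (default 30).
#' @param m Lines per drift-correction block (default 2); must satisfy
#'   `1 <= m <= nx`.
#' @param reposition Logical: apply the block repositioning protocol
#'   (default `TRUE`).
#' @param t_spectrum Seconds per spectrum (default 1.66).
#' @param topo_time Seconds per topography image between blocks (default 12).
#' @param origin `c(y, x)` scene pixel of the window's top-left corner
#'   (default `c(1, 1)`); a window smaller than the scene leaves margin for
#'   uncorrected drift.
#' @param tip_frequency Tip oscillation frequency Omega in Hz (metadata).
#' @param demodulation_order Demodulation harmonic n (metadata, default 3).
#' @return An object of class `nf_scan_plan`.
#' @export
scan_plan <- function(shape, pixel_size = 30, m = 2L, reposition = TRUE,
                      t_spectrum = 1.66, topo_time = 12, origin = c(1L, 1L),
                      tip_frequency = 250e3, demodulation_order = 3L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L), t_spectrum > 0,
            demodulation_order >= 1L)
  if (m < 1L || m > shape[2])
    stop("m must satisfy 1 <= m <= number of lines", call. = FALSE)
  structure(list(shape = shape, pixel_size = pixel_size, m = as.integer(m),
                 reposition = isTRUE(reposition), t_spectrum = t_spectrum,
                 topo_time = topo_time, origin = as.integer(origin),
                 tip_frequency = tip_frequency,
                 demodulation_order = as.integer(demodulation_order)),
            class = "nf_scan_plan")
}

#' Sample-stage drift trajectory
#'
#' Stage offset `(dx, dy)` in nm as a function of elapsed scan time:
#' a linear rate plus an optional slow sinusoid, with `offset(0) = (0, 0)`.
#'
#' @param rate `c(x, y)` drift rate in nm/s (default `c(0.07, 0.05)`, a
#'   thermal-drift magnitude that accumulates to tens of pixels over an
#'   hours-long scan but stays below one 30 nm pixel within a 2-line block).
#' @param sine_amp `c(x, y)` sinusoid amplitudes in nm (default `c(15, 10)`).
#' @param sine_period Sinusoid period in seconds (default 2400).
#' @return An object of class `nf_drift`; call it or its `$offset(t)`.
#' @export
drift_trajectory <- function(rate = c(0.07, 0.05), sine_amp = c(15, 10),
                             sine_period = 2400) {
  force(rate); force(sine_amp); force(sine_period)
  offset <- function(t)
    c(rate[1] * t + sine_amp[1] * sin(2 * pi * t / sine_period),
      rate[2] * t + sine_amp[2] * sin(2 * pi * t / sine_period))
  structure(list(offset = offset, rate = rate, sine_amp = sine_amp,
                 sine_period = sine_period), class = "nf_drift")
}

no_drift <- function() drift_trajectory(c(0, 0), c(0, 0), 1)

#' Estimate stage drift from two topography images
#'
#' Displacement at the peak of the circular normalized cross-correlation of
#' the two mean-centred images, with optional parabolic sub-pixel
#' refinement. The returned shift `(dx, dy)` is defined so that
#' `now[y, x] ~ ref[y + dy, x + dx]`, i.e. it is the sampling offset that
#' produced `now` from `ref`.
#'
#' @param topo_ref,topo_now Matrices of equal shape with nonzero variance.
#' @param subpixel Logical: parabolic peak interpolation (default `TRUE`).
#' @return `c(dx, dy)` in pixels.
#' @export
estimate_stage_drift <- function(topo_ref, topo_now, subpixel = TRUE) {
  if (!all(dim(topo_ref) == dim(topo_now)))
    stop("topography images must have equal shape", call. = FALSE)
  a <- topo_ref - mean(topo_ref)
  b <- topo_now - mean(topo_now)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("flat topography image: correlation undefined", call. = FALSE)
  C <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  pk <- which(C == max(C), arr.ind = TRUE)[1, ]
  n <- dim(C)
  wrap <- function(i, size) ifelse(i - 1 > size / 2, i - 1 - size, i - 1)
  shift <- c(dy = wrap(pk[1], n[1]), dx = wrap(pk[2], n[2]))
  if (subpixel) {
    at <- function(dy, dx)
      C[((pk[1] - 1 + dy) %% n[1]) + 1, ((pk[2] - 1 + dx) %% n[2]) + 1]
    para <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (den == 0) 0 else 0.5 * (cm - cp) / den
    }
    shift[1] <- shift[1] + para(at(-1, 0), at(0, 0), at(1, 0))
    shift[2] <- shift[2] + para(at(0, -1), at(0, 0), at(0, 1))
  }
  c(dx = unname(shift[2]), dy = unname(shift[1]))
}

#' Normalize a line of spectra against its reference spectrum
#'
#' Complex ratio against the line's reference: amplitude `s = s_s / s_ref`
#' and wrapped phase difference `phi = phi_s - phi_ref` per pixel. The
#' reference spectrum itself normalizes to `s = 1`, `phi = 0` on the band
#' support to machine precision.
#'
#' @param line_spectra Complex matrix (pixels x frequencies) or a single
#'   complex vector / `nf_spectrum`.
#' @param reference Complex reference spectrum (same grid) or `nf_spectrum`.
#' @param support Optional logical vector: band support on which the
#'   reference amplitude must be bounded away from zero.
#' @return List with `amplitude`, `phase` (degrees, wrapped), `ratio`
#'   (complex).
#' @export
normalize_line <- function(line_spectra, reference, support = NULL) {
  if (inherits(line_spectra, "nf_spectrum")) line_spectra <- line_spectra$values
  if (inherits(reference, "nf_spectrum")) reference <- reference$values
  if (is.null(dim(line_spectra)))
    line_spectra <- matrix(line_spectra, nrow = 1)
  if (ncol(line_spectra) != length(reference))
    stop("line and reference must share the frequency grid", call. = FALSE)
  amp_ref <- Mod(reference)
  chk <- if (is.null(support)) amp_ref else amp_ref[support]
  if (max(amp_ref) == 0 || any(chk < 1e-10 * max(amp_ref)))
    stop("degenerate reference: amplitude vanishes on band support",
         call. = FALSE)
  ratio <- sweep(line_spectra, 2L, reference, `/`)
  list(amplitude = Mod(ratio), phase = wrap_deg(rad2deg(Arg(ratio))),
       ratio = ratio)
}

#' Acquisition time accounting
#'
#' `n_bands * (n_spectra * t_spectrum + overhead_per_band) / 3600` hours.
#' One 82 x 62 = 5084-spectrum cube at 1.66 s per spectrum takes 2.34 h;
#' three cubes with 10 min repositioning overhead each take about 7.5 h.
#'
#' @param n_spectra Spectra per cube (>= 0).
#' @param t_spectrum Seconds per spectrum (>= 0).
#' @param n_bands Number of band cubes (default 1).
#' @param overhead_per_band Extra seconds per cube, e.g. for repositioning
#'   (default 0).
#' @return Time in hours.
#' @export
estimate_acquisition_time <- function(n_spectra, t_spectrum, n_bands = 1,
                                      overhead_per_band = 0) {
  stopifnot(n_spectra >= 0, t_spectrum >= 0, n_bands >= 0,
            overhead_per_band >= 0)
  n_bands * (n_spectra * t_spectrum + overhead_per_band) / 3600
}

#' Simulate the raster scan of one laser band
#'
#' Scans the scene in the documented order (reference spectrum, then the
#' pixels of each line; lines left to right), sampling the scene at the
#' drifted stage position (nearest neighbour), simulating and reconstructing
#' each pixel's interferogram and normalizing every line against its silicon
#' reference spectrum. With `plan$reposition` on, the scan pauses after
#' each block of `m` lines, records a topography image, estimates the
#' accumulated stage offset against the initial topography by
#' cross-correlation and repositions the scanner; all block corrections are
#' logged. Interferometer path drift is modelled per line (piecewise
#' constant within a line) and applied to the sample pixels only - the
#' physical drift accumulates between the reference and sample
#' acquisitions, so it survives line normalization as a phase offset.
#'
#' @param scene An `nf_scene`.
#' @param envelope An [laser_envelope()].
#' @param plan An [scan_plan()]; defaults to the full scene.
#' @param stage_drift An [drift_trajectory()] or `NULL` for none.
#' @param interferometer_drift Path drift per line in cm: scalar, vector of
#'   length `nx`, a `function(line) -> delta`, or `NULL` for none.
#' @param noise_sd Detector noise standard deviation (interferogram units).
#' @param seed Optional seed (scan noise, topography roughness).
#' @param positions Mirror positions (default [default_positions()]).
#' @param pad_factor,apodization Passed to the spectrum reconstruction.
#' @param topo_noise_sd Topography roughness noise in nm (default 2).
#' @param keep_raw Logical: retain the raw interferograms (default `FALSE`).
#' @return An object of class `nf_band_cube`: `band_id`, `grid` (the scene
#'   grid), `phase` and `amplitude` arrays `[ny, nx, nfreq]`, `support`,
#'   `envelope`, `meta`, `topo_blocks`, `drift_log`
#'   (block/line/estimated/residual offsets in px), `reference` (complex
#'   reference spectra per line), `interferometer_drift` (cm per line), and
#'   optionally `raw`.
#' @export
simulate_scan <- function(scene, envelope, plan = NULL, stage_drift = NULL,
                          interferometer_drift = NULL, noise_sd = 0,
                          seed = NULL, positions = default_positions(),
                          pad_factor = 4, apodization = "none",
                          topo_noise_sd = 2, keep_raw = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(plan)) plan <- scan_plan(scene$shape, scene$pixel_size)
  ny <- plan$shape[1]; nx <- plan$shape[2]
  oy <- plan$origin[1]; ox <- plan$origin[2]
  if (oy + ny - 1L > scene$shape[1] || ox + nx - 1L > scene$shape[2])
    stop("scan window exceeds scene", call. = FALSE)
  if (is.null(stage_drift)) stage_drift <- no_drift()
  delta_line <- interferometer_drift_per_line(interferometer_drift, nx)
  px <- plan$pixel_size
  nu <- scene$grid$values
  nfreq <- length(nu)
  dd <- positions[2] - positions[1]

  # mapping from the padded FFT grid onto the scene grid (must align)
  probe <- spectra_matrix(matrix(0, 1, length(positions)), dd, pad_factor,
                          apodization, range = c(800, 2100))
  qmap <- match(round(nu / probe$grid$resolution, 6),
                round(probe$grid$values / probe$grid$resolution, 6))
  if (anyNA(qmap))
    stop("scene grid is not a subset of the reconstruction grid; ",
         "adjust positions/pad_factor", call. = FALSE)

  silicon <- rep(1 + 0i, nfreq)
  phase <- array(NA_real_, c(ny, nx, nfreq))
  amplitude <- array(NA_real_, c(ny, nx, nfreq))
  refs <- matrix(NA_complex_, nx, nfreq)
  raw <- if (keep_raw) array(NA_real_, c(ny, nx, length(positions))) else NULL
  raw_ref <- if (keep_raw) matrix(NA_real_, nx, length(positions)) else NULL

  topo0 <- render_topography(scene, c(0, 0), topo_noise_sd)
  topo_blocks <- list()
  log_rows <- list()
  corr <- c(0, 0)    # accumulated repositioning correction, nm (x, y)
  t_now <- 0

  for (ix in seq_len(nx)) {
    t_now <- t_now + plan$t_spectrum          # reference spectrum
    t_pix <- t_now + plan$t_spectrum * seq_len(ny)
    t_now <- t_pix[ny]
    off <- vapply(t_pix, stage_drift$offset, numeric(2))  # 2 x ny (x, y)
    iy_s <- clamp_idx(round(oy - 1L + seq_len(ny) + (off[2, ] - corr[2]) / px),
                      scene$shape[1])
    ix_s <- clamp_idx(round(ox - 1L + ix + (off[1, ] - corr[1]) / px),
                      scene$shape[2])
    Sigma <- scene_sigma(scene, iy_s, ix_s)
    I_line <- interferogram_matrix(Sigma, envelope, positions,
                                   delta_line[ix], noise_sd)
    I_ref <- interferogram_matrix(matrix(silicon, nrow = 1), envelope,
                                  positions, 0, noise_sd)
    sp <- spectra_matrix(rbind(I_ref, I_line), dd, pad_factor, apodization,
                         range = c(800, 2100))
    vals <- sp$values[, qmap, drop = FALSE]
    norm <- normalize_line(vals[-1, , drop = FALSE], vals[1, ],
                           support = envelope$support)
    phase[, ix, ] <- norm$phase
    amplitude[, ix, ] <- norm$amplitude
    refs[ix, ] <- vals[1, ]
    if (keep_raw) { raw[, ix, ] <- I_line; raw_ref[ix, ] <- I_ref[1, ] }

    if (plan$reposition && ix %% plan$m == 0L && ix < nx) {
      t_now <- t_now + plan$topo_time
      net <- (stage_drift$offset(t_now) - corr) / px
      topo_now <- render_topography(scene, net, topo_noise_sd)
      est <- estimate_stage_drift(topo0, topo_now)
      corr <- corr + est * px
      resid <- (stage_drift$offset(t_now) - corr) / px
      topo_blocks[[length(topo_blocks) + 1L]] <- topo_now
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(block = length(log_rows) + 1L, line = ix,
                   est_dx_px = est[1], est_dy_px = est[2],
                   residual_dx_px = resid[1], residual_dy_px = resid[2])
    }
  }
  drift_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(block = integer(0), line = integer(0), est_dx_px = numeric(0),
               est_dy_px = numeric(0), residual_dx_px = numeric(0),
               residual_dy_px = numeric(0))
  structure(list(
    band_id = envelope$band_id, grid = scene$grid, shape = c(ny, nx),
    phase = phase, amplitude = amplitude, support = envelope$support,
    envelope = envelope,
    meta = list(tip_frequency = plan$tip_frequency,
                demodulation_order = plan$demodulation_order,
                t_spectrum = plan$t_spectrum, band_id = envelope$band_id,
                center = envelope$center, bandwidth = envelope$bandwidth,
                m = plan$m, reposition = plan$reposition,
                pixel_size = plan$pixel_size, origin = plan$origin,
                nominal_resolution_cm1 = 1 / (length(positions) * dd),
                pad_factor = pad_factor, apodization = apodization,
                total_time_s = t_now),
    topo_blocks = topo_blocks, drift_log = drift_log, reference = refs,
    interferometer_drift = delta_line,
    raw = if (keep_raw) list(interferograms = raw, reference = raw_ref,
                             positions = positions) else NULL),
    class = "nf_band_cube")
}

interferometer_drift_per_line <- function(x, nx) {
  if (is.null(x)) return(rep(0, nx))
  if (is.function(x)) return(vapply(seq_len(nx), x, numeric(1)))
  if (length(x) == 1L) return(rep(x, nx))
  if (length(x) != nx)
    stop("interferometer_drift must be scalar, length-nx, or a function",
         call. = FALSE)
  x
}

#' @export
print.nf_band_cube <- function(x, ...) {
  cat(sprintf(
    "<nf_band_cube> band %s (%.0f cm-1), %d x %d px, %d frequencies\n",
    x$band_id, x$meta$center, x$shape[1], x$shape[2], length(x$grid$values)))
  invisible(x)
}
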
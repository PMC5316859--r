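#' Mirror positions of the one-sided interferogram record
#'
#' Optical path difference samples `d = 0, dd, ..., (n-1) dd` in cm, starting
#' at zero path difference (ZPD). The defaults (`n = 512`,
#' `dd = 1/4480 cm`) give a Nyquist frequency of 2240 cm^-1 and a nominal
#' spectral resolution of `1/(n*dd) = 8.75 cm^-1`, matching
#' [default_grid()].
#'
#' @param n Number of samples (default 512).
#' @param delta_d Mirror step in cm (default 1/4480).
#' @return Numeric vector of positions in cm.
#' @export
default_positions <- function(n = 512L, delta_d = 1 / 4480) {
  (seq_len(n) - 1) * delta_d
}

#' Gaussian laser band envelope
#'
#' Spectral power envelope of one bandwidth-limited laser output. The
#' Gaussian width is chosen so that the support at the `threshold` fraction
#' of the maximum has exactly the requested effective bandwidth.
#'
#' @param band_id Band label, conventionally one of `"I"`, `"II"`, `"III"`.
#' @param center Centre wavenumber in cm^-1.
#' @param bandwidth Effective bandwidth in cm^-1 at the support threshold
#'   (default 350).
#' @param grid Frequency grid (default [default_grid()]).
#' @param threshold Support threshold as a fraction of the envelope maximum
#'   (default 0.2).
#' @return An object of class `nf_envelope` with fields `band_id`, `center`,
#'   `bandwidth`, `grid`, `values` (non-negative, max 1), `support`
#'   (logical), `threshold`.
#' @export
laser_envelope <- function(band_id, center, bandwidth = 350,
                           grid = default_grid(), threshold = 0.2) {
  if (!inherits(grid, "nf_grid")) grid <- frequency_grid(grid)
  stopifnot(center > 0, bandwidth > 0, threshold > 0, threshold < 1)
  sg <- bandwidth / (2 * sqrt(2 * log(1 / threshold)))
  v <- exp(-(grid$values - center)^2 / (2 * sg^2))
  structure(list(band_id = band_id, center = center, bandwidth = bandwidth,
                 grid = grid, values = v, support = v >= threshold * max(v),
                 threshold = threshold),
            class = "nf_envelope")
}

#' Default three-band laser configuration
#'
#' Band centres 1170, 1450 and 1730 cm^-1 with 350 cm^-1 effective
#' bandwidth: the supports overlap pairwise (I,II) and (II,III) and their
#' union covers roughly 1000-1900 cm^-1.
#'
#' @param grid Frequency grid.
#' @param bandwidth,threshold Passed to [laser_envelope()].
#' @return Named list of three `nf_envelope` objects (`I`, `II`, `III`).
#' @export
default_bands <- function(grid = default_grid(), bandwidth = 350,
                          threshold = 0.2) {
  centers <- c(I = 1170, II = 1450, III = 1730)
  stats::setNames(
    lapply(names(centers), function(k)
      laser_envelope(k, centers[[k]], bandwidth, grid, threshold)),
    names(centers))
}

# internal batch forward model: Sigma [npx x nfreq] complex responses ->
# real interferogram matrix [npx x nd].
# I(d) = Re[ sum_w E(w) sigma(w) exp(i 2 pi w (d + delta)) dw ] + noise
interferogram_matrix <- function(Sigma, envelope, positions, path_drift = 0,
                                 noise_sd = 0) {
  nu <- envelope$grid$values
  dnu <- envelope$grid$resolution
  if (ncol(Sigma) != length(nu))
    stop("response and envelope must share the frequency grid", call. = FALSE)
  phase <- exp(1i * 2 * pi * outer(nu, positions + path_drift))  # nfreq x nd
  weighted <- sweep(Sigma, 2L, envelope$values * dnu, `*`)
  out <- Re(weighted %*% phase)
  if (noise_sd > 0)
    out <- out + matrix(stats::rnorm(length(out), 0, noise_sd),
                        nrow(out), ncol(out))
  out
}

#' Simulate a one-sided nano-FTIR interferogram
#'
#' Detector record of the asymmetric Michelson spectrometer for one pixel
#' and one laser band: `I(d) = Re[ sum_w E(w) sigma(w) exp(i 2 pi w (d +
#' delta)) dw ] + N(0, noise_sd)`, sampled on a one-sided mirror track
#' starting at ZPD. A relative path drift `delta` of the reference arm
#' enters as the common shift `d -> d + delta`.
#'
#' @param response Complex response `sigma(w)` on the envelope grid, or an
#'   `nf_component`.
#' @param envelope An [laser_envelope()].
#' @param positions Mirror positions in cm from [default_positions()].
#' @param path_drift Relative interferometer path error `delta` in cm
#'   (default 0; 100 nm = 1e-5 cm).
#' @param noise_sd Gaussian detector noise standard deviation (same units as
#'   the interferogram values).
#' @param seed Optional integer seed for the noise.
#' @return Object of class `nf_interferogram`: `positions`, `values`,
#'   `band_id`, `meta` (`delta_d`, `n`, `nominal_resolution_cm1`,
#'   `path_drift`).
#' @export
simulate_interferogram <- function(response, envelope, positions = default_positions(),
                                   path_drift = 0, noise_sd = 0, seed = NULL) {
  if (inherits(response, "nf_component")) response <- response$response
  if (!is.null(seed)) set.seed(seed)
  if (length(positions) < 2L) stop("need at least two positions", call. = FALSE)
  dd <- diff(positions)
  if (abs(positions[1]) > 1e-15 || max(abs(dd - dd[1])) > 1e-12 * dd[1])
    stop("positions must be uniform starting at zero path difference",
         call. = FALSE)
  vals <- interferogram_matrix(matrix(response, nrow = 1), envelope,
                               positions, path_drift, noise_sd)[1, ]
  structure(list(positions = positions, values = vals,
                 band_id = envelope$band_id,
                 meta = list(delta_d = dd[1], n = length(positions),
                             nominal_resolution_cm1 = 1 / (length(positions) * dd[1]),
                             path_drift = path_drift)),
            class = "nf_interferogram")
}

# internal batch inverse: I [npx x nd] -> complex spectra [npx x nq] on the
# padded FFT grid restricted to `range`. Plain (unweighted) DFT of the
# one-sided record: for spectra whose energy lies on the reconstruction
# grid this is the exact inverse of the forward model above.
spectra_matrix <- function(I, delta_d, pad_factor = 4,
                           apodization = c("none", "hann"),
                           range = c(800, 2100)) {
  apodization <- match.arg(apodization)
  n <- ncol(I); npx <- nrow(I)
  if (apodization == "hann") {
    w <- 0.5 * (1 + cos(pi * (0:(n - 1)) / (n - 1)))  # half-Hann, 1 at ZPD
    I <- sweep(I, 2L, w, `*`)
  }
  np <- n * pad_factor
  padded <- cbind(I, matrix(0, npx, np - n))
  S <- t(stats::mvfft(t(padded)))                      # npx x np
  dnu <- 1 / (np * delta_d)
  q <- seq(0L, np - 1L)
  keep <- which(q * dnu >= range[1] & q * dnu <= range[2])
  list(grid = frequency_grid(q[keep] * dnu), values = S[, keep, drop = FALSE],
       nominal_resolution = 1 / (n * delta_d))
}

#' Recover a complex spectrum from a one-sided interferogram
#'
#' Complex FFT of the one-sided record (ZPD sample first) with optional
#' half-Hann apodization and zero padding; the returned grid is the padded
#' FFT frequency axis restricted to `range`. The nominal resolution
#' `1/(n * delta_d)` (before padding) is reported in the metadata.
#'
#' @param interferogram An `nf_interferogram` (>= 64 samples).
#' @param pad_factor Zero-padding factor (default 4).
#' @param apodization `"none"` (default; preserves phase exactly in the
#'   discrete-tone world) or `"hann"` (half-Hann window).
#' @param range Wavenumber interval to keep, cm^-1 (default `c(800, 2100)`).
#' @return Object of class `nf_spectrum`: `grid`, `values` (complex),
#'   `amplitude`, `phase` (degrees in (-180, 180]), `band_id`, `meta`.
#' @export
spectrum_from_interferogram <- function(interferogram, pad_factor = 4,
                                        apodization = c("none", "hann"),
                                        range = c(800, 2100)) {
  ig <- interferogram
  if (length(ig$values) < 64L)
    stop("need at least 64 interferogram samples", call. = FALSE)
  dd <- diff(ig$positions)
  if (max(abs(dd - dd[1])) > 1e-12 * dd[1])
    stop("non-uniform mirror positions", call. = FALSE)
  sp <- spectra_matrix(matrix(ig$values, nrow = 1), dd[1], pad_factor,
                       apodization, range)
  vals <- sp$values[1, ]
  structure(list(grid = sp$grid, values = vals, amplitude = Mod(vals),
                 phase = rad2deg(Arg(vals)), band_id = ig$band_id,
                 meta = list(nominal_resolution_cm1 = sp$nominal_resolution,
                             pad_factor = pad_factor,
                             apodization = match.arg(apodization))),
            class = "nf_spectrum")
}

#' Phase offset produced by interferometer path drift
#'
#' First-order phase of `exp(i 2 pi nu delta)`: a relative drift `delta`
#' (cm) of the reference arm against the tip arm offsets the normalized
#' phase spectrum at wavenumber `nu` (cm^-1) by `360 * nu * delta` degrees.
#' For example, 100 nm of drift gives about 6 degrees at 1660 cm^-1.
#'
#' @param nu Wavenumber(s) in cm^-1 (> 0).
#' @param delta Path drift in cm (1 nm = 1e-7 cm).
#' @return Phase offset(s) in degrees.
#' @seealso [path_drift_for_offset()] for the inverse relation.
#' @export
phase_offset_from_path_drift <- function(nu, delta) {
  if (any(nu <= 0)) stop("nu must be > 0", call. = FALSE)
  360 * nu * delta
}

#' Path stability required for a given phase offset
#'
#' Inverse of [phase_offset_from_path_drift()]: the path drift (cm) that
#' produces `delta_phi` degrees of phase offset at wavenumber `nu`.
#'
#' @param nu Wavenumber in cm^-1 (> 0).
#' @param delta_phi Phase offset in degrees.
#' @return Path drift in cm.
#' @export
path_drift_for_offset <- function(nu, delta_phi) {
  if (any(nu <= 0)) stop("nu must be > 0", call. = FALSE)
  delta_phi / (360 * nu)
}
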
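#' Vibrational oscillator
#'
#' One Lorentzian oscillator of the phenomenological material response used
#' by the synthetic scenes.
#'
#' @param center Resonance wavenumber in cm^-1 (> 0).
#' @param strength Dimensionless oscillator amplitude (>= 0). For a single
#'   weak oscillator on a unit background the peak phase is approximately
#'   `atan(strength / (width * center))`; [oscillator_strength()] inverts
#'   this relation.
#' @param width Damping width in cm^-1 (> 0); roughly the FWHM of the phase
#'   feature in the weak-oscillator regime.
#' @return A one-row `data.frame` with columns `center`, `strength`, `width`.
#' @export
oscillator <- function(center, strength, width) {
  if (!is.finite(center) || center <= 0) stop("center must be > 0", call. = FALSE)
  if (!is.finite(width) || width <= 0) stop("width must be > 0", call. = FALSE)
  if (!is.finite(strength) || strength < 0) stop("strength must be >= 0", call. = FALSE)
  data.frame(center = center, strength = strength, width = width)
}

#' Oscillator strength for a target peak phase
#'
#' Inverts the weak-oscillator relation: at resonance a single oscillator on
#' a real unit background contributes `strength / (width * center)` to the
#' imaginary part, i.e. a phase of about `atan` of that ratio.
#'
#' @param peak_deg Target peak phase in degrees.
#' @param center,width Oscillator position and damping width, cm^-1.
#' @return Strength value for [oscillator()].
#' @export
oscillator_strength <- function(peak_deg, center, width) {
  tan(deg2rad(peak_deg)) * width * center
}

#' Complex component response
#'
#' Evaluates the phenomenological complex response of one material on a
#' frequency grid as a sum of Lorentzian oscillators over a (generally
#' complex) non-resonant background:
#' sigma(w) = background + sum_j strength_j / (center_j^2 - w^2 - i width_j w).
#' The phase spectrum is `Arg(sigma)` in degrees, the amplitude `Mod(sigma)`.
#'
#' @param oscillators A `data.frame` with columns `center`, `strength`,
#'   `width` (e.g. built by rbind-ing [oscillator()] rows), or `NULL` /
#'   zero rows for a non-resonant material.
#' @param background Complex non-resonant response (default `1+0i`).
#' @param grid An [frequency_grid()] (or numeric wavenumber vector).
#' @param name Optional text label.
#' @return An object of class `nf_component`: fields `name`, `grid`,
#'   `oscillators`, `background`, `response` (complex), `amplitude`,
#'   `phase` (degrees, in (-180, 180]).
#' @export
component_response <- function(oscillators, background = 1 + 0i, grid,
                               name = "") {
  if (missing(grid) || length(grid_values(grid)) == 0L)
    stop("empty frequency grid", call. = FALSE)
  if (!inherits(grid, "nf_grid")) grid <- frequency_grid(grid)
  if (length(background) != 1L || is.na(background) ||
      !is.finite(Mod(as.complex(background))))
    stop("background must be a single finite complex value", call. = FALSE)
  w <- grid$values
  sig <- rep(as.complex(background), length(w))
  if (!is.null(oscillators) && nrow(as.data.frame(oscillators)) > 0L) {
    oscillators <- as.data.frame(oscillators)
    stopifnot(all(c("center", "strength", "width") %in% names(oscillators)))
    if (any(oscillators$center <= 0) || any(oscillators$width <= 0) ||
        any(oscillators$strength < 0))
      stop("invalid oscillator parameters", call. = FALSE)
    for (j in seq_len(nrow(oscillators))) {
      o <- oscillators[j, ]
      sig <- sig + o$strength / (o$center^2 - w^2 - 1i * o$width * w)
    }
  } else {
    oscillators <- data.frame(center = numeric(0), strength = numeric(0),
                              width = numeric(0))
  }
  if (any(!is.finite(Re(sig))) || any(!is.finite(Im(sig))))
    stop("non-finite component response", call. = FALSE)
  structure(list(name = name, grid = grid, oscillators = oscillators,
                 background = as.complex(background), response = sig,
                 amplitude = Mod(sig), phase = rad2deg(Arg(sig))),
            class = "nf_component")
}

#' @export
print.nf_component <- function(x, ...) {
  cat(sprintf("<nf_component> '%s': %d oscillator(s), peak phase %.1f deg\n",
              x$name, nrow(x$oscillators), max(abs(x$phase))))
  invisible(x)
}

#' Built-in component spectra
#'
#' Phenomenological stand-ins for the pure-material phase spectra used by the
#' synthetic scenes. Band positions follow the vibrational assignments of the
#' materials (acrylic copolymer C=O 1740 and ester C-O 1155 cm^-1; fluorine
#' copolymer CF2 1195 cm^-1; polystyrene weak aromatic bands; keratin amide
#' I/II 1660/1550 cm^-1; melanin 1290, 1454, 1563, 1638 cm^-1). Peak phase
#' amplitudes are in the 5-20 degree range typical of nano-FTIR phase
#' spectra of organics. The "FP:AC interaction" component models hydrogen
#' bonding between the two polymers: the CF2 stretch shifts from 1195 down to
#' 1155 cm^-1 where it adds to an enhanced ester band, while the C=O
#' contribution is reduced.
#'
#' @param grid Frequency grid (default [default_grid()]).
#' @return Named list of `nf_component` objects: `AC`, `FP`, `PS`,
#'   `interaction`, `keratin`, `melanin`, `resin`, `silicon`.
#' @export
component_library <- function(grid = default_grid()) {
  os <- function(...) do.call(rbind, list(...))
  o <- function(center, peak_deg, width)
    oscillator(center, oscillator_strength(peak_deg, center, width), width)
  list(
    AC = component_response(os(
      o(1740, 14, 45), o(1155, 10, 50), o(1450, 5, 55), o(1385, 3, 50)),
      grid = grid, name = "AC"),
    FP = component_response(os(
      o(1195, 14, 45), o(1400, 6, 50), o(1070, 4, 55)),
      grid = grid, name = "FP"),
    PS = component_response(os(
      o(1493, 4, 28), o(1452, 3, 30), o(1601, 2.5, 25)),
      grid = grid, name = "PS"),
    interaction = component_response(os(
      o(1155, 20, 60), o(1740, 5, 45), o(1400, 5, 50), o(1450, 4, 55)),
      grid = grid, name = "FP:AC interaction"),
    keratin = component_response(os(
      o(1660, 16, 55), o(1550, 12, 60), o(1450, 4, 60), o(1240, 4, 70)),
      grid = grid, name = "keratin"),
    melanin = component_response(os(
      o(1290, 10, 50), o(1454, 8, 48), o(1563, 9, 45), o(1638, 11, 45)),
      grid = grid, name = "melanin"),
    resin = component_response(NULL, background = 1.05 + 0i, grid = grid,
                               name = "resin"),
    silicon = component_response(NULL, background = 1 + 0i, grid = grid,
                                 name = "silicon")
  )
}

#' Export a phase spectrum as a two-column CSV
#'
#' Writes `wavenumber_cm-1, phase_deg` (comma separator, dot decimal,
#' header row, UTF-8).
#'
#' @param grid Frequency grid or numeric wavenumbers.
#' @param phase Numeric phase values in degrees (same length as grid).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_spectrum_csv <- function(grid, phase, path) {
  v <- grid_values(grid)
  stopifnot(length(v) == length(phase))
  df <- data.frame(`wavenumber_cm-1` = v, phase_deg = as.numeric(phase),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
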
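# Cube bundles: plain-text serialization of scenes, band cubes, hypercubes
# and analysis products. A bundle is a directory with meta.json plus one CSV
# per dataset; matrices are stored pixel-major (rows = pixels in column-major
# pixel order, i.e. pixel p = (ix-1)*ny + iy), spectra columns = frequencies.
# Units: phase deg, frequency cm-1, lengths nm. Schema version "1".

NF_SCHEMA_VERSION <- "1"

write_matrix_csv <- function(M, path) {
  utils::write.table(M, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
}

read_matrix_csv <- function(path, what = double()) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              colClasses = "numeric"))
}

flatten_cube <- function(a) {
  dm <- dim(a)
  matrix(a, prod(dm[1:2]), dm[3])
}

unflatten_cube <- function(M, shape) {
  array(M, c(shape[1], shape[2], ncol(M)))
}

require_dataset <- function(dir, name) {
  p <- file.path(dir, name)
  if (!file.exists(p))
    stop(sprintf("schema error: bundle is missing dataset '%s'", name),
         call. = FALSE)
  p
}

write_meta <- function(dir, meta) {
  meta$schema_version <- NF_SCHEMA_VERSION
  meta$units <- list(phase = "deg", frequency = "cm-1", length = "nm")
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_meta <- function(dir) {
  p <- require_dataset(dir, "meta.json")
  meta <- jsonlite::read_json(p, simplifyVector = TRUE)
  if (!identical(meta$schema_version, NF_SCHEMA_VERSION))
    stop(sprintf("schema error: unsupported schema version '%s'",
                 meta$schema_version), call. = FALSE)
  meta
}

#' Write a cube bundle
#'
#' Serializes a scene, band cube or hypercube (plus analysis labels) as a
#' plain-text bundle: a directory holding `meta.json` (class, shape, units,
#' attributes, schema version) and one CSV per dataset. The layout is
#' self-describing and round-trips losslessly through [read_cube()].
#'
#' @param x An `nf_scene`, `nf_band_cube` or `nf_hypercube`.
#' @param path Bundle directory (created/overwritten).
#' @return `path`, invisibly.
#' @export
write_cube <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "nf_scene")) {
    write_meta(path, list(class = "nf_scene", shape = x$shape,
                          pixel_size = x$pixel_size, seed = x$seed,
                          label_names = x$label_names,
                          compositions = x$compositions))
    write_matrix_csv(matrix(x$grid$values, ncol = 1),
                     file.path(path, "frequency.csv"))
    write_matrix_csv(x$labels, file.path(path, "truth_labels.csv"))
    write_matrix_csv(flatten_cube(x$truth_phase),
                     file.path(path, "truth_phase.csv"))
    write_matrix_csv(flatten_cube(x$truth_amplitude),
                     file.path(path, "truth_amplitude.csv"))
    write_matrix_csv(x$height, file.path(path, "height.csv"))
  } else if (inherits(x, "nf_band_cube")) {
    write_meta(path, list(class = "nf_band_cube", shape = x$shape,
                          band_id = x$band_id, attrs = x$meta))
    write_matrix_csv(matrix(x$grid$values, ncol = 1),
                     file.path(path, "frequency.csv"))
    write_matrix_csv(flatten_cube(x$phase), file.path(path, "phase.csv"))
    write_matrix_csv(flatten_cube(x$amplitude),
                     file.path(path, "amplitude.csv"))
    write_matrix_csv(matrix(as.integer(x$support), ncol = 1),
                     file.path(path, "support.csv"))
    utils::write.csv(x$drift_log, file.path(path, "drift_log.csv"),
                     row.names = FALSE)
  } else if (inherits(x, "nf_hypercube")) {
    write_meta(path, list(class = "nf_hypercube", shape = x$shape,
                          pixel_size = x$pixel_size,
                          anchors = x$provenance$baseline,
                          bands = x$provenance$bands))
    write_matrix_csv(matrix(x$grid$values, ncol = 1),
                     file.path(path, "frequency.csv"))
    write_matrix_csv(flatten_cube(x$phase), file.path(path, "phase.csv"))
    if (!is.null(x$provenance$offset_I))
      write_matrix_csv(x$provenance$offset_I,
                       file.path(path, "offset_I.csv"))
    if (!is.null(x$provenance$offset_III))
      write_matrix_csv(x$provenance$offset_III,
                       file.path(path, "offset_III.csv"))
  } else stop("unsupported object for write_cube", call. = FALSE)
  invisible(path)
}

#' Read a cube bundle
#'
#' @param path Bundle directory written by [write_cube()].
#' @return The deserialized object (`nf_scene` bundles are returned as a
#'   plain list with truth datasets; cubes regain their class).
#' @export
read_cube <- function(path) {
  meta <- read_meta(path)
  g <- frequency_grid(read_matrix_csv(require_dataset(path, "frequency.csv"))[, 1])
  shape <- as.integer(meta$shape)
  if (identical(meta$class, "nf_band_cube")) {
    phase <- unflatten_cube(read_matrix_csv(require_dataset(path, "phase.csv")),
                            shape)
    amplitude <- unflatten_cube(
      read_matrix_csv(require_dataset(path, "amplitude.csv")), shape)
    support <- as.logical(
      read_matrix_csv(require_dataset(path, "support.csv"))[, 1])
    drift_log <- utils::read.csv(file.path(path, "drift_log.csv"))
    structure(list(band_id = meta$band_id, grid = g, shape = shape,
                   phase = phase, amplitude = amplitude, support = support,
                   envelope = NULL, meta = meta$attrs,
                   topo_blocks = list(), drift_log = drift_log,
                   reference = NULL, interferometer_drift = NULL, raw = NULL),
              class = "nf_band_cube")
  } else if (identical(meta$class, "nf_hypercube")) {
    phase <- unflatten_cube(read_matrix_csv(require_dataset(path, "phase.csv")),
                            shape)
    prov <- list(baseline = meta$anchors, bands = meta$bands)
    for (nm in c("offset_I", "offset_III")) {
      p <- file.path(path, paste0(nm, ".csv"))
      if (file.exists(p)) prov[[nm]] <- read_matrix_csv(p)
    }
    structure(list(grid = g, phase = phase, shape = shape,
                   pixel_size = meta$pixel_size, provenance = prov),
              class = "nf_hypercube")
  } else if (identical(meta$class, "nf_scene")) {
    list(meta = meta, grid = g,
         truth_labels = read_matrix_csv(require_dataset(path, "truth_labels.csv")),
         truth_phase = unflatten_cube(
           read_matrix_csv(require_dataset(path, "truth_phase.csv")), shape),
         truth_amplitude = unflatten_cube(
           read_matrix_csv(require_dataset(path, "truth_amplitude.csv")), shape),
         height = read_matrix_csv(require_dataset(path, "height.csv")))
  } else stop(sprintf("schema error: unknown bundle class '%s'", meta$class),
              call. = FALSE)
}

#' Export a pixel spectrum from a cube as CSV
#'
#' @param cube `nf_hypercube` or `nf_band_cube`.
#' @param x,y Pixel indices (1-based column/row).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_pixel_csv <- function(cube, x, y, path) {
  stopifnot(y >= 1, y <= cube$shape[1], x >= 1, x <= cube$shape[2])
  export_spectrum_csv(cube$grid, cube$phase[y, x, ], path)
}

#' Export a map as an 8-bit PNG
#'
#' Distance maps are written greyscale (bright = small distance), composite
#' maps as RGB, cluster label maps with a fixed qualitative palette.
#'
#' @param map An `nf_distmap`, `nf_composite`, `nf_clusters`, or a numeric
#'   matrix (rescaled to greyscale).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_map_png <- function(map, path) {
  if (inherits(map, "nf_distmap")) {
    D <- map$values
    rng <- range(D)
    v <- if (rng[2] > rng[1]) 1 - (D - rng[1]) / (rng[2] - rng[1]) else
      matrix(1, nrow(D), ncol(D))
    img <- array(v, c(dim(D), 3L))
  } else if (inherits(map, "nf_composite")) {
    img <- map$values
  } else if (inherits(map, "nf_clusters")) {
    pal <- grDevices::col2rgb(nf_cluster_palette(max(map$labels))) / 255
    img <- array(0, c(dim(map$labels), 3L))
    for (ch in 1:3)
      img[, , ch] <- matrix(pal[ch, map$labels], nrow(map$labels))
  } else {
    D <- as.matrix(map)
    rng <- range(D)
    v <- if (rng[2] > rng[1]) (D - rng[1]) / (rng[2] - rng[1]) else D * 0
    img <- array(v, c(dim(D), 3L))
  }
  ny <- dim(img)[1]; nx <- dim(img)[2]
  grDevices::png(path, width = nx, height = ny)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, 1, 1,
                        interpolate = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Fixed cluster-map palette
#'
#' @param k Number of clusters.
#' @return Character vector of k colours.
#' @export
nf_cluster_palette <- function(k) {
  base <- c("#2166AC", "#F4A6C0", "#1B9E52", "#D6231F", "#4D4D4D",
            "#F7E625", "#8C510A", "#7B3294")
  rep(base, length.out = k)
}

# raw interferogram bundle (for the reconstruct CLI stage)
write_raw_bundle <- function(cube, path) {
  if (is.null(cube$raw))
    stop("band cube was simulated without keep_raw = TRUE", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_meta(path, list(class = "nf_raw", shape = cube$shape,
                        band_id = cube$band_id, attrs = cube$meta,
                        envelope = list(center = cube$envelope$center,
                                        bandwidth = cube$envelope$bandwidth,
                                        threshold = cube$envelope$threshold)))
  write_matrix_csv(matrix(cube$raw$positions, ncol = 1),
                   file.path(path, "positions.csv"))
  write_matrix_csv(matrix(cube$grid$values, ncol = 1),
                   file.path(path, "frequency.csv"))
  write_matrix_csv(flatten_cube(cube$raw$interferograms),
                   file.path(path, "interferograms.csv"))
  write_matrix_csv(cube$raw$reference, file.path(path, "reference.csv"))
  invisible(path)
}

#' Reconstruct a band cube from a raw interferogram bundle
#'
#' Rebuilds a band cube from stored one-sided interferograms: Fourier
#' reconstruction of every pixel and per-line normalization to the stored
#' reference interferograms.
#'
#' @param path Raw bundle directory (written by the `simulate --raw` CLI
#'   stage).
#' @param pad_factor,apodization Reconstruction settings.
#' @return An `nf_band_cube`.
#' @export
reconstruct_band_cube <- function(path, pad_factor = 4,
                                  apodization = "none") {
  meta <- read_meta(path)
  if (!identical(meta$class, "nf_raw"))
    stop("schema error: not a raw interferogram bundle", call. = FALSE)
  shape <- as.integer(meta$shape)
  positions <- read_matrix_csv(require_dataset(path, "positions.csv"))[, 1]
  g <- frequency_grid(read_matrix_csv(require_dataset(path, "frequency.csv"))[, 1])
  I <- read_matrix_csv(require_dataset(path, "interferograms.csv"))
  Iref <- read_matrix_csv(require_dataset(path, "reference.csv"))
  env <- laser_envelope(meta$band_id, meta$envelope$center,
                        meta$envelope$bandwidth, g, meta$envelope$threshold)
  dd <- positions[2] - positions[1]
  probe <- spectra_matrix(matrix(0, 1, length(positions)), dd, pad_factor,
                          apodization, range = c(800, 2100))
  qmap <- match(round(g$values / probe$grid$resolution, 6),
                round(probe$grid$values / probe$grid$resolution, 6))
  ny <- shape[1]; nx <- shape[2]
  phase <- array(NA_real_, c(ny, nx, length(g$values)))
  amplitude <- array(NA_real_, c(ny, nx, length(g$values)))
  for (ix in seq_len(nx)) {
    rows <- (ix - 1L) * ny + seq_len(ny)
    sp <- spectra_matrix(rbind(Iref[ix, ], I[rows, , drop = FALSE]), dd,
                         pad_factor, apodization, range = c(800, 2100))
    vals <- sp$values[, qmap, drop = FALSE]
    norm <- normalize_line(vals[-1, , drop = FALSE], vals[1, ],
                           support = env$support)
    phase[, ix, ] <- norm$phase
    amplitude[, ix, ] <- norm$amplitude
  }
  structure(list(band_id = meta$band_id, grid = g, shape = shape,
                 phase = phase, amplitude = amplitude,
                 support = env$support, envelope = env, meta = meta$attrs,
                 topo_blocks = list(),
                 drift_log = data.frame(), reference = NULL,
                 interferometer_drift = NULL, raw = NULL),
            class = "nf_band_cube")
}
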
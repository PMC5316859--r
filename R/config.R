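#' Run configuration
#'
#' Fully-resolved configuration of a simulation + analysis run. All
#' randomness in a run flows from the single `seed`. Overrides are
#' deep-merged into the defaults, which are the package's stated
#' experimental conditions: three 350 cm^-1 laser bands centred at 1170,
#' 1450 and 1730 cm^-1; a 512-sample one-sided interferogram with mirror
#' step 1/4480 cm (8.75 cm^-1 nominal resolution) and pad factor 4; a 62 x
#' 82 px blend scene at 30 nm/px scanned in 1.66 s per spectrum with the
#' m = 2 repositioning protocol; slow thermal stage drift; per-band
#' interferometer path offsets of up to 115 nm per band (so that two bands
#' can be offset against each other by up to about 12 degrees mid-band)
#' with a small per-line random walk; detector
#' noise giving sub-degree phase noise at band centre; baseline anchors
#' 1030 and 1870 cm^-1; Ward/D-value clustering over 1000-1850 cm^-1 with
#' K = 5.
#'
#' @param ... Named overrides (nested lists), e.g.
#'   `nf_config(scene = list(shape = c(20, 24)), seed = 7)`.
#' @return Nested list of class `nf_config`.
#' @export
nf_config <- function(...) {
  defaults <- list(
    seed = 0L,
    scene = list(type = "blend", shape = c(62L, 82L), pixel_size = 30),
    bands = list(centers = c(1170, 1450, 1730), bandwidth = 350,
                 threshold = 0.2),
    interferometer = list(n_positions = 512L, delta_d = 1 / 4480,
                          pad_factor = 4L, apodization = "none"),
    scan = list(m = 2L, reposition = TRUE, t_spectrum = 1.66,
                topo_time = 12),
    stage_drift = list(rate = c(0.07, 0.05), sine_amp = c(15, 10),
                       sine_period = 2400),
    interferometer_drift = list(base_nm = 115, walk_sd_nm = 3),
    noise = list(interferogram_sd = 0.7, topo_sd_nm = 2),
    anchors = c(1030, 1870),
    analysis = list(hca_range = c(1000, 1850), n_clusters = 5L)
  )
  cfg <- merge_config(defaults, list(...))
  class(cfg) <- c("nf_config", "list")
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read / write a run configuration as JSON
#'
#' Configurations round-trip losslessly (numeric precision preserved);
#' values read from file are merged over the defaults.
#'
#' @param config An [nf_config()].
#' @param path JSON file path.
#' @return `write_config`: `path` invisibly; `read_config`: `nf_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(nf_config, raw)
}

# djb-style rolling hash of the serialized config, for run logs
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 33 + b) %% 2147483648     # stays exact in double precision
  sprintf("%08x", as.integer(h))
}

#' Run the full simulation + reconstruction + analysis pipeline
#'
#' Generates the configured scene, simulates the three band acquisitions
#' (stage drift, per-line interferometer drift, detector noise,
#' per-line silicon referencing, block repositioning), corrects per-pixel
#' phase offsets, stitches, baseline-corrects, and runs the multivariate
#' analysis (Ward/D-value clustering; distance maps against the pure
#' references for blend scenes). Every run can be logged to `out_dir`
#' with the resolved configuration, its hash, the seed and stage timings.
#'
#' @param config An [nf_config()].
#' @param out_dir Optional output directory for bundles, maps and the run
#'   log.
#' @param keep_raw Retain/write raw interferograms (default `FALSE`).
#' @param verbose Print stage progress.
#' @return List with `scene`, `band_cubes`, `corrected`, `hypercube`
#'   (baseline-corrected), `clusters`, `ari` (vs truth labels),
#'   `distance_maps`, `config`.
#' @export
run_pipeline <- function(config = nf_config(), out_dir = NULL,
                         keep_raw = FALSE, verbose = FALSE) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
    if (verbose) message(sprintf("[%7.2fs] %s", timings[[stage]], stage))
  }
  grid <- default_grid()
  scene <- switch(config$scene$type,
    blend = make_blend_scene(config$scene$shape, config$scene$pixel_size,
                             seed = config$seed, grid = grid),
    hair = make_hair_scene(config$scene$shape, config$scene$pixel_size,
                           seed = config$seed, grid = grid),
    stop("unknown scene type", call. = FALSE))
  tick("scene")

  centers <- config$bands$centers
  bands <- stats::setNames(lapply(1:3, function(k)
    laser_envelope(c("I", "II", "III")[k], centers[k],
                   config$bands$bandwidth, grid, config$bands$threshold)),
    c("I", "II", "III"))
  plan <- scan_plan(config$scene$shape, config$scene$pixel_size,
                    m = config$scan$m, reposition = config$scan$reposition,
                    t_spectrum = config$scan$t_spectrum,
                    topo_time = config$scan$topo_time)
  drift <- drift_trajectory(config$stage_drift$rate,
                            config$stage_drift$sine_amp,
                            config$stage_drift$sine_period)
  positions <- default_positions(config$interferometer$n_positions,
                                 config$interferometer$delta_d)
  nx <- plan$shape[2]
  cubes <- list()
  for (k in c("I", "II", "III")) {
    base <- stats::runif(1, -config$interferometer_drift$base_nm,
                         config$interferometer_drift$base_nm)
    walk <- cumsum(stats::rnorm(nx, 0, config$interferometer_drift$walk_sd_nm))
    delta <- (base + walk) * 1e-7            # nm -> cm
    cubes[[k]] <- simulate_scan(
      scene, bands[[k]], plan, stage_drift = drift,
      interferometer_drift = delta,
      noise_sd = config$noise$interferogram_sd,
      positions = positions,
      pad_factor = config$interferometer$pad_factor,
      apodization = config$interferometer$apodization,
      topo_noise_sd = config$noise$topo_sd_nm, keep_raw = keep_raw)
    tick(paste0("band_", k))
  }

  corrected <- correct_offsets(cubes$I, cubes$II, cubes$III)
  weights <- build_weights(corrected$cubes, grid)
  hyper <- stitch(corrected, weights)
  hyper <- baseline_correct(hyper, anchors = config$anchors)
  tick("stitch")

  clusters <- hca(hyper, config$analysis$n_clusters,
                  range = config$analysis$hca_range)
  ari <- adjusted_rand_index(scene$labels, clusters$labels)
  dmaps <- NULL
  if (config$scene$type == "blend") {
    refs <- component_library(grid)
    r_ac <- baseline_correct(refs$AC$phase, config$anchors, grid)
    r_fp <- baseline_correct(refs$FP$phase, config$anchors, grid)
    dmaps <- list(
      AC = euclidean_distance_map(hyper, stats::approx(
        grid$values, r_ac, xout = hyper$grid$values)$y, name = "AC"),
      FP = euclidean_distance_map(hyper, stats::approx(
        grid$values, r_fp, xout = hyper$grid$values)$y, name = "FP"))
  }
  tick("analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cube(scene, file.path(out_dir, "scene"))
    for (k in names(cubes)) {
      write_cube(cubes[[k]], file.path(out_dir, paste0("band_", k)))
      if (keep_raw)
        write_raw_bundle(cubes[[k]], file.path(out_dir, paste0("raw_", k)))
    }
    write_cube(hyper, file.path(out_dir, "hypercube"))
    write_matrix_csv(clusters$labels, file.path(out_dir, "labels.csv"))
    utils::write.csv(
      data.frame(wavenumber = hyper$grid$values, t(clusters$means),
                 check.names = FALSE),
      file.path(out_dir, "cluster_means.csv"), row.names = FALSE)
    export_map_png(clusters, file.path(out_dir, "cluster_map.png"))
    if (!is.null(dmaps)) {
      export_map_png(dmaps$AC, file.path(out_dir, "distance_AC.png"))
      export_map_png(dmaps$FP, file.path(out_dir, "distance_FP.png"))
      export_map_png(composite_map(dmaps, c("red", "blue")),
                     file.path(out_dir, "composite.png"))
    }
    tick("export")
    log <- list(config = unclass(config), config_hash = config_hash(config),
                seed = config$seed, timings = timings, ari = ari,
                offset_summary = list(
                  offset_I_mean = mean(corrected$offset_I),
                  offset_III_mean = mean(corrected$offset_III)),
                anchors = config$anchors)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(scene = scene, band_cubes = cubes, corrected = corrected,
                 hypercube = hyper, clusters = clusters, ari = ari,
                 distance_maps = dmaps, config = config))
}
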
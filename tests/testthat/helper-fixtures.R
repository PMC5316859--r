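# shared fixtures; expensive pipeline runs are cached across test files
nf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(nf_cache[[key]])) nf_cache[[key]] <- force(expr)
  nf_cache[[key]]
}

noiseless_config <- function(...) {
  nf_config(noise = list(interferogram_sd = 0),
            stage_drift = list(rate = c(0, 0), sine_amp = c(0, 0)),
            interferometer_drift = list(base_nm = 0, walk_sd_nm = 0), ...)
}

default_run <- function() cached("default", run_pipeline(nf_config()))
noiseless_run <- function() cached("noiseless", run_pipeline(noiseless_config()))

# minimal hypercube-like object for mva unit tests
make_toy_cube <- function(phase, grid) {
  if (!inherits(grid, "nf_grid")) grid <- frequency_grid(grid)
  structure(list(grid = grid, phase = phase,
                 shape = dim(phase)[1:2], pixel_size = 30,
                 provenance = list(baseline = NULL)),
            class = "nf_hypercube")
}

# baseline-corrected truth phase of a scene, on the scene grid
truth_baselined <- function(scene, anchors = c(1030, 1870)) {
  dm <- dim(scene$truth_phase)
  flat <- matrix(scene$truth_phase, prod(dm[1:2]), dm[3])
  array(baseline_correct(flat, anchors, scene$grid), dm)
}

# RMS of (hypercube - baseline-corrected truth) over [lo, hi]
truth_rms <- function(res, lo = 1030, hi = 1870) {
  hyper <- res$hypercube
  idx_h <- which(hyper$grid$values >= lo & hyper$grid$values <= hi)
  idx_s <- match(round(hyper$grid$values[idx_h], 6),
                 round(res$scene$grid$values, 6))
  tb <- truth_baselined(res$scene)[, , idx_s, drop = FALSE]
  sqrt(mean((hyper$phase[, , idx_h, drop = FALSE] - tb)^2))
}

# pure-reference phase spectra, baseline-corrected and resampled to a cube
# grid, restricted to the anchor interval
unmix_refs <- function(scene, hyper, anchors = c(1030, 1870)) {
  comps <- component_library(scene$grid)
  bc <- function(p) baseline_correct(p, anchors, scene$grid)
  g <- hyper$grid$values
  sel <- which(g >= anchors[1] & g <= anchors[2])
  list(refs = cbind(
    FP = stats::approx(scene$grid$values, bc(comps$FP$phase), xout = g)$y[sel],
    AC = stats::approx(scene$grid$values, bc(comps$AC$phase), xout = g)$y[sel]),
    sel = sel)
}

# 3x3 neighbourhood average restricted to pixels sharing the centre label
label_avg_spectrum <- function(hyper, labels, y, x, sel) {
  dm <- dim(hyper$phase)
  ys <- max(1, y - 1):min(dm[1], y + 1)
  xs <- max(1, x - 1):min(dm[2], x + 1)
  cells <- expand.grid(y = ys, x = xs)
  cells <- cells[labels[cbind(cells$y, cells$x)] == labels[y, x], ]
  rowMeans(apply(cells, 1, function(p) hyper$phase[p[1], p[2], sel]))
}

# interior pixels of a label (full 3x3 window same label)
label_interior <- function(labels, l) {
  ny <- nrow(labels); nx <- ncol(labels)
  ok <- matrix(FALSE, ny, nx)
  for (y in 2:(ny - 1)) for (x in 2:(nx - 1))
    ok[y, x] <- all(labels[(y - 1):(y + 1), (x - 1):(x + 1)] == l)
  which(ok, arr.ind = TRUE)
}
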
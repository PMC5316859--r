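# ---- helpers ------------------------------------------------------------

cube_matrix <- function(cube, idx = NULL) {
  dm <- dim(cube$phase)
  M <- matrix(cube$phase, prod(dm[1:2]), dm[3])
  if (!is.null(idx)) M <- M[, idx, drop = FALSE]
  M
}

as_reference_spectrum <- function(reference, grid) {
  g <- grid_values(grid)
  if (inherits(reference, "nf_component")) {
    if (max(abs(reference$grid$values - g)) > 1e-9)
      reference <- stats::approx(reference$grid$values, reference$phase,
                                 xout = g, rule = 2)$y
    else reference <- reference$phase
  }
  if (length(reference) != length(g))
    stop("reference must be on the cube grid", call. = FALSE)
  as.numeric(reference)
}

#' Euclidean inter-spectral distance map
#'
#' Per-pixel Euclidean distance `sqrt(sum_w (phi - phi_ref)^2)` between the
#' cube's phase spectra and a reference spectrum over an analysis range.
#'
#' @param cube An `nf_hypercube` (or `nf_band_cube`).
#' @param reference Reference phase spectrum (numeric on the cube grid, or
#'   an `nf_component`, resampled if needed).
#' @param range Optional `c(lo, hi)` cm^-1 (default: full cube range).
#' @param name Label for the reference.
#' @return Object of class `nf_distmap`: `values` matrix (>= 0), `range`,
#'   `reference_name`.
#' @export
euclidean_distance_map <- function(cube, reference, range = NULL,
                                   name = deparse(substitute(reference))) {
  idx <- grid_range_idx(cube$grid, range)
  ref <- as_reference_spectrum(reference, cube$grid)
  M <- cube_matrix(cube, idx)
  d <- sqrt(rowSums(sweep(M, 2L, ref[idx], `-`)^2))
  structure(list(values = matrix(d, dim(cube$phase)[1], dim(cube$phase)[2]),
                 range = if (is.null(range)) range(cube$grid$values) else range,
                 reference_name = name),
            class = "nf_distmap")
}

#' Composite colour map from distance maps
#'
#' Converts each distance map to an intensity with the monotone decreasing
#' scaling `intensity = 1 - (D - D_lo) / (D_hi - D_lo)` (percentile-clipped
#' at 2/98 by default, so high colour intensity denotes a low
#' inter-spectral distance), multiplies by the map's hue and sums the RGB
#' channels, clipping to [0, 1]. Pixels far from every reference come out
#' black; pixels equally (and intermediately) close to a red and a blue
#' reference come out purple.
#'
#' @param distance_maps List of >= 2 `nf_distmap`s (equal shapes).
#' @param hues Character colours, one per map (default `c("red", "blue")`).
#' @param clip Percentile clipping probabilities (default `c(0.02, 0.98)`).
#' @return Object of class `nf_composite`: array `[ny, nx, 3]` in [0, 1].
#' @export
composite_map <- function(distance_maps, hues = c("red", "blue"),
                          clip = c(0.02, 0.98)) {
  stopifnot(length(distance_maps) >= 2L,
            length(hues) == length(distance_maps))
  shp <- dim(distance_maps[[1]]$values)
  rgb_sum <- array(0, c(shp, 3L))
  for (i in seq_along(distance_maps)) {
    D <- distance_maps[[i]]$values
    if (!all(dim(D) == shp))
      stop("distance maps must share the same shape", call. = FALSE)
    q <- stats::quantile(D, clip, names = FALSE)
    intensity <- if (q[2] > q[1]) 1 - (D - q[1]) / (q[2] - q[1]) else
      matrix(1, shp[1], shp[2])
    intensity <- pmin(pmax(intensity, 0), 1)
    hue <- grDevices::col2rgb(hues[i])[, 1] / 255
    for (ch in 1:3)
      rgb_sum[, , ch] <- rgb_sum[, , ch] + intensity * hue[ch]
  }
  structure(list(values = pmin(rgb_sum, 1), hues = hues),
            class = "nf_composite")
}

#' D-value inter-spectral distance
#'
#' `D = (1 - r) * 1000` with `r` the Pearson correlation of the two spectra
#' over the analysis range - the standard inter-spectral distance of IR
#' spectroscopy cluster analysis. `D` lies in [0, 2000], is symmetric,
#' invariant under affine rescaling of either spectrum, and zero iff the
#' spectra are perfectly correlated.
#'
#' @param spec_a,spec_b Numeric phase spectra on a common grid.
#' @param grid Frequency grid (needed when `range` is given).
#' @param range Optional `c(lo, hi)` cm^-1 (>= 3 points).
#' @return Dimensionless distance in [0, 2000].
#' @export
d_value <- function(spec_a, spec_b, grid = NULL, range = NULL) {
  if (!is.null(range)) {
    if (is.null(grid)) stop("grid required with range", call. = FALSE)
    idx <- grid_range_idx(grid, range)
    spec_a <- spec_a[idx]; spec_b <- spec_b[idx]
  }
  if (length(spec_a) < 3L)
    stop("need at least 3 points in range", call. = FALSE)
  if (stats::sd(spec_a) == 0 || stats::sd(spec_b) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  (1 - stats::cor(spec_a, spec_b)) * 1000
}

d_value_matrix <- function(X) {
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance spectrum: correlation undefined", call. = FALSE)
  D <- (1 - stats::cor(t(X))) * 1000
  D[D < 0] <- 0      # numerical guard
  D
}

#' Hierarchical cluster analysis of a hypercube
#'
#' Segments the cube by agglomerative clustering of the pairwise D-value
#' matrix (see [d_value()]) over the analysis range, using Ward's method
#' applied directly to the D-values via the Lance-Williams update
#' (`stats::hclust(method = "ward.D")`). The tree is cut at `n_clusters`
#' and labels are renumbered by descending cluster size (ties broken by the
#' lowest member pixel index; the agglomeration itself is deterministic
#' given the cube). Per-cluster mean and standard-deviation spectra are
#' computed over the full cube range.
#'
#' @param cube An `nf_hypercube` (or `nf_band_cube`).
#' @param n_clusters Number of clusters K (>= 1, <= number of pixels).
#' @param range Analysis range in cm^-1 (default `c(1000, 1850)`).
#' @return Object of class `nf_clusters`: `labels` (integer matrix 1..K),
#'   `heights` (Ward merge heights), `means`/`sds` (K x nfreq), `sizes`,
#'   `range`, `hclust`.
#' @export
hca <- function(cube, n_clusters, range = c(1000, 1850)) {
  idx <- grid_range_idx(cube$grid, range)
  X <- cube_matrix(cube, idx)
  n <- nrow(X)
  if (n_clusters < 1L || n_clusters > n)
    stop("n_clusters must be between 1 and the number of pixels",
         call. = FALSE)
  if (n_clusters == 1L) {
    labels <- rep(1L, n)
    hc <- NULL; heights <- numeric(0)
  } else {
    D <- d_value_matrix(X)
    hc <- stats::hclust(stats::as.dist(D), method = "ward.D")
    heights <- hc$height
    labels <- stats::cutree(hc, k = n_clusters)
  }
  # renumber by descending size, ties by lowest member index
  tab <- table(labels)
  first <- vapply(names(tab), function(l) min(which(labels == as.integer(l))),
                  numeric(1))
  ord <- order(-as.integer(tab), first)
  remap <- integer(length(tab))
  remap[as.integer(names(tab))[ord]] <- seq_along(ord)
  labels <- remap[labels]
  lab_mat <- matrix(labels, dim(cube$phase)[1], dim(cube$phase)[2])
  st <- cluster_stats(cube, lab_mat)
  structure(list(labels = lab_mat, heights = heights, means = st$mean,
                 sds = st$sd, sizes = st$sizes, range = range,
                 n_clusters = n_clusters, hclust = hc),
            class = "nf_clusters")
}

#' @export
print.nf_clusters <- function(x, ...) {
  cat(sprintf("<nf_clusters> K = %d, sizes: %s\n", x$n_clusters,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Per-cluster mean and standard-deviation spectra
#'
#' @param cube An `nf_hypercube` (or `nf_band_cube`).
#' @param labels Integer label matrix partitioning the pixels (1..K).
#' @return List with `mean` and `sd` (K x nfreq matrices; population sd),
#'   `sizes`. Empty clusters are flagged with `NA` statistics.
#' @export
cluster_stats <- function(cube, labels) {
  M <- cube_matrix(cube)
  lv <- as.integer(labels)
  K <- max(lv)
  nfreq <- ncol(M)
  mu <- matrix(NA_real_, K, nfreq)
  sdv <- matrix(NA_real_, K, nfreq)
  sizes <- integer(K)
  for (k in seq_len(K)) {
    sel <- which(lv == k)
    sizes[k] <- length(sel)
    if (length(sel) == 0L) next
    Mk <- M[sel, , drop = FALSE]
    mu[k, ] <- colMeans(Mk)
    sdv[k, ] <- sqrt(colMeans(sweep(Mk, 2L, mu[k, ], `-`)^2))
  }
  list(mean = mu, sd = sdv, sizes = sizes)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings of the same pixels.
#'
#' @param a,b Integer label vectors/matrices of equal length.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# ---- unmixing -----------------------------------------------------------

# Lawson-Hanson non-negative least squares with optionally free columns
nnls_ls <- function(A, b, free = rep(FALSE, ncol(A))) {
  m <- ncol(A)
  passive <- free
  x <- rep(0, m)
  solve_ls <- function(cols) {
    fit <- qr(A[, cols, drop = FALSE])
    qr.coef(fit, b)
  }
  if (any(passive)) {        # free columns enter the fit unconditionally
    x[passive] <- solve_ls(which(passive))
    x[is.na(x)] <- 0
  }
  for (outer in seq_len(10L * m + 10L)) {
    w <- drop(crossprod(A, b - A %*% x))
    cand <- which(!passive & !free)
    if (length(cand) == 0L || max(w[cand]) <= 1e-10 * max(1, max(abs(w))))
      break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      z <- rep(0, m)
      z[passive] <- solve_ls(which(passive))
      z[is.na(z)] <- 0
      neg <- which(passive & !free & z < 0)
      if (length(neg) == 0L) { x <- z; break }
      cur <- which(passive & !free & z < 0)
      alpha <- min(x[cur] / (x[cur] - z[cur]))
      x <- x + alpha * (z - x)
      passive[passive & !free & x <= 1e-12] <- FALSE
      x[!passive] <- 0
    }
  }
  x
}

#' Linear spectral unmixing
#'
#' Least-squares fit of a phase spectrum as a linear superposition of
#' reference spectra, `phi ~ sum_i c_i phi_ref_i (+ c0)`, with optional
#' non-negativity of the coefficients (Lawson-Hanson active set) and an
#' optional free constant offset (phase baselines may retain small
#' constants).
#'
#' @param spectrum Numeric phase spectrum.
#' @param references Matrix (nfreq x m) of reference spectra, a list of
#'   `nf_component`s, or a single numeric reference.
#' @param allow_offset Include a free constant term (default `TRUE`).
#' @param nonneg Constrain reference coefficients to be >= 0 (default
#'   `TRUE`).
#' @return Object of class `nf_unmix`: `coefficients` (named), `offset`,
#'   `fitted`, `residual_rms` (degrees), `r_squared`, `collinear` flag.
#' @export
unmix <- function(spectrum, references, allow_offset = TRUE, nonneg = TRUE) {
  b <- as.numeric(spectrum)
  if (is.list(references) && !is.data.frame(references))
    references <- vapply(references, function(r)
      if (inherits(r, "nf_component")) r$phase else as.numeric(r),
      numeric(length(b)))
  A <- as.matrix(references)
  if (nrow(A) != length(b))
    stop("spectrum and references must share the grid", call. = FALSE)
  m <- ncol(A)
  if (is.null(colnames(A))) colnames(A) <- paste0("ref", seq_len(m))
  collinear <- FALSE
  if (m > 1L) {
    sv <- svd(scale(A, center = FALSE, scale = sqrt(colSums(A^2))))$d
    if (min(sv) < 1e-8 * max(sv)) {
      collinear <- TRUE
      warning("reference spectra are (nearly) collinear", call. = FALSE)
    }
  }
  design <- if (allow_offset) cbind(A, offset = 1) else A
  free <- c(rep(!nonneg, m), if (allow_offset) TRUE)
  x <- nnls_ls(design, b, free = free)
  fitted <- drop(design %*% x)
  res <- b - fitted
  sstot <- sum((b - mean(b))^2)
  structure(list(
    coefficients = stats::setNames(x[seq_len(m)], colnames(A)),
    offset = if (allow_offset) x[m + 1L] else 0,
    fitted = fitted, residual_rms = sqrt(mean(res^2)),
    r_squared = if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_,
    collinear = collinear), class = "nf_unmix")
}

#' @export
print.nf_unmix <- function(x, ...) {
  cat(sprintf("<nf_unmix> coefficients: %s; offset %.3g; residual RMS %.3g deg; R2 %.4f\n",
              paste(sprintf("%s=%.3f", names(x$coefficients), x$coefficients),
                    collapse = ", "),
              x$offset, x$residual_rms, x$r_squared))
  invisible(x)
}

#' Linear-superposition test
#'
#' Declares a spectrum a linear superposition of the references iff the
#' unmixing residual RMS is at or below a threshold. The recommended
#' threshold is 3x the median residual of known-pure pixels
#' ([superposition_threshold()]).
#'
#' @inheritParams unmix
#' @param threshold Residual RMS threshold in degrees.
#' @return List with `superposition` (logical), `unmix` (the fit),
#'   `threshold`.
#' @export
superposition_test <- function(spectrum, references, threshold,
                               allow_offset = TRUE, nonneg = TRUE) {
  fit <- unmix(spectrum, references, allow_offset, nonneg)
  list(superposition = fit$residual_rms <= threshold, unmix = fit,
       threshold = threshold)
}

#' Superposition threshold from known-pure pixels
#'
#' 3x the median unmixing residual of spectra known to be pure (or true
#' mixtures) at the working noise level.
#'
#' @param spectra Matrix (n x nfreq) of known-pure/known-mixture spectra.
#' @param references As in [unmix()].
#' @param factor Multiplier (default 3).
#' @return Threshold in degrees.
#' @export
superposition_threshold <- function(spectra, references, factor = 3,
                                    allow_offset = TRUE, nonneg = TRUE) {
  res <- apply(spectra, 1L, function(s)
    unmix(s, references, allow_offset, nonneg)$residual_rms)
  factor * stats::median(res)
}
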
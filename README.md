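# nanoftir

Simulation and multivariate analysis of **hyperspectral nano-FTIR phase
imaging** — infrared nanospectroscopy in which a metallic AFM tip scatters
a bandwidth-limited mid-IR laser continuum and an asymmetric Michelson
interferometer records, pixel by pixel, one-sided interferograms whose
Fourier transform yields nanoscale-resolved phase spectra
$\phi(x, y, \omega)$. Broadband cubes covering ~1000–1900 cm⁻¹ are built
by stitching three ~350 cm⁻¹ laser bands at every pixel.

The package is for people developing or validating processing chains for
such data (and for band-stitched FTIR imaging generally): it provides the
whole pipeline end to end against synthetic scenes with known ground
truth, so every correction step can be tested quantitatively.

## What it implements

1. **Scenes** (`make_blend_scene()`, `make_hair_scene()`) — label maps of a
   three-component polymer blend (acrylic / fluoropolymer / polystyrene,
   with chemically "interacting" rims) and a hair cross-section with
   melanin granules; per-material complex responses are Lorentzian
   oscillator sums
   $\sigma(\omega) = b + \sum_j s_j/(\omega_j^2-\omega^2-i\gamma_j\omega)$,
   and mixed volumes are convex combinations of the pure *phase* spectra.
2. **Interferometry** (`simulate_interferogram()`,
   `spectrum_from_interferogram()`) — one-sided records
   $I(d)=\mathrm{Re}\sum_\omega E\sigma\,e^{i2\pi\omega(d+\delta)}\Delta\omega$
   and their FFT reconstruction; interferometer path drift $\delta$ offsets
   the normalized phase by $\Delta\phi = 360\,\nu\,\delta$ degrees
   (100 nm → ≈ 6° at 1660 cm⁻¹; < 1° at 1400 cm⁻¹ needs ≈ 20 nm stability).
3. **Acquisition** (`simulate_scan()`) — raster scan with per-line silicon
   referencing, slow stage drift, and the block repositioning protocol
   (after each *m* lines a topography image is registered by
   cross-correlation and the scanner is repositioned).
4. **Stitching** (`correct_offsets()`, `build_weights()`, `stitch()`,
   `baseline_correct()`) — per-pixel circular-mean phase offsets in the
   band overlaps, linear-ramp partition-of-unity weights, and two-anchor
   linear baseline correction.
5. **Multivariate analysis** (`euclidean_distance_map()`,
   `composite_map()`, `hca()`, `unmix()`, `superposition_test()`) —
   distance and composite maps, Ward hierarchical clustering on Pearson
   D-values $D=(1-r)\cdot1000$ over 1000–1850 cm⁻¹, per-cluster mean/sd
   spectra, and non-negative least-squares unmixing against pure reference
   spectra to separate true mixtures from chemically modified
   ("interaction") spectra.
6. **IO + CLI** — plain-text cube bundles (`write_cube()`/`read_cube()`),
   CSV/PNG export, JSON run configs, and a command-line tool
   (`inst/cli/nanoftir`, subcommands `simulate`, `reconstruct`, `stitch`,
   `analyze`, `export`, `pipeline`).

## Worked example

```r
library(nanoftir)
res <- run_pipeline(nf_config(scene = list(shape = c(20, 24))))
res$hypercube
#> <nf_hypercube> 20 x 24 px, 997.5 - 1899 cm-1 (104 points), baseline-corrected
res$clusters
#> <nf_clusters> K = 5, sizes: 299, 67, 46, 44, 24
cat(sprintf("ARI vs ground-truth labels: %.2f\n", res$ari))
#> ARI vs ground-truth labels: 0.93
phase_offset_from_path_drift(1660, 100e-7)   # 100 nm drift, degrees
#> [1] 5.976
estimate_acquisition_time(82 * 62, 1.66)     # one band cube, hours
#> [1] 2.344284
```

`run_pipeline()` simulates the scene, scans it in three laser bands under
stage and interferometer drift with detector noise, reconstructs and
normalizes every spectrum, corrects the per-pixel inter-band phase offsets
(up to ~12°), stitches, baseline-corrects at 1030/1870 cm⁻¹ and clusters
the cube. The ARI of 0.93 says the five recovered clusters essentially
match the five ground-truth regions; the last two numbers reproduce the
instrument's drift error budget and acquisition-time accounting.

The same run from the shell, with all artifacts written to `out/`:

```sh
Rscript inst/cli/nanoftir pipeline --seed 0 --out out
Rscript inst/cli/nanoftir analyze --in out/hypercube --k 5 --out out/ana --truth out/scene
```

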
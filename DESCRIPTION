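Package: nanoftir
Title: Simulation and Multivariate Analysis of Hyperspectral nano-FTIR Phase Imaging
Version: 0.1.0
Authors@R:
    person("nanoftir", "maintainers", email = "maintainers@nanoftir.dev", role = c("aut", "cre"))
Description: Tools for simulating and analysing hyperspectral infrared
    nanoimaging experiments based on Fourier transform infrared
    nanospectroscopy (nano-FTIR) with a tunable bandwidth-limited laser
    continuum. The package generates synthetic organic test scenes
    (Lorentzian-oscillator component spectra on ground-truth label maps),
    simulates one-sided asymmetric-Michelson interferograms per laser band
    including interferometer path drift, sample-stage drift, per-line
    reference spectra and detector noise, reconstructs complex spectra by
    Fourier transform, and stitches the band-limited phase cubes into a
    broadband hyperspectral cube with per-pixel phase-offset correction,
    weighted band merging and two-anchor linear baseline correction.
    Multivariate analysis of the resulting cubes includes Euclidean
    inter-spectral distance maps, composite colour maps, Ward hierarchical
    clustering on Pearson D-values, per-cluster statistics and non-negative
    linear spectral unmixing with superposition testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
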
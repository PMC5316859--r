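---
title: "Stitched hyperspectral nano-FTIR imaging: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitched hyperspectral nano-FTIR imaging: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoftir)
```

## The measurement this package simulates

nano-FTIR spectroscopy records, at each pixel of an AFM scan, the light
backscattered from a metallic tip with an asymmetric Michelson
interferometer. Because tip and sample sit in one interferometer arm, the
Fourier transform of the one-sided interferogram $I(d)$ yields both an
amplitude and a phase spectrum; for organic materials the normalized phase
$\phi(\omega)$ tracks far-field absorbance and is the quantity analysed
here. A tunable mid-infrared laser continuum delivers only a
bandwidth-limited (~350 cm$^{-1}$) spectrum at a time, so a broadband
hyperspectral cube is built by recording three overlapping band-limited
cubes $A^k = \phi^k(x, y, \omega)$, $k \in \{\mathrm{I,II,III}\}$, and
stitching them per pixel. The package implements the full chain —
synthetic scene, raster acquisition with drift, Fourier reconstruction,
per-line referencing, per-pixel offset correction, weighted stitching,
baseline correction, multivariate analysis — so that every processing step
can be validated against a known ground truth.

## Forward model and its exact inverse

The detector record for one pixel and band is

$$I(d_j) = \mathrm{Re}\!\left[\sum_\omega E(\omega)\,\sigma(\omega)\,
  e^{\,i 2\pi \omega (d_j + \delta)}\,\Delta\omega\right] + \varepsilon_j,$$

with $E$ the laser envelope, $\sigma$ the pixel's complex response,
$\delta$ the relative interferometer path drift and $\varepsilon_j$
Gaussian detector noise. Mirror positions are one-sided, $d_j = j\,\Delta d$
from zero path difference.

Two deliberate numerical choices follow from this *discrete-tone* world:

* **Grid commensurability.** All spectra live on a uniform grid with step
  8.75 cm$^{-1}$ (805–2100 cm$^{-1}$), and the default record has
  $n = 512$ samples with $\Delta d = 1/4480$ cm, i.e. mirror travel
  $n\,\Delta d = 1/8.75$ cm. Every grid tone is then orthogonal over the
  record, and the plain zero-padded DFT of the one-sided record inverts
  the forward model *exactly* (to machine precision). All stitching and
  analysis errors measured by the test suite are therefore attributable to
  the disturbances under study (noise, drift, offsets), not to transform
  leakage.
* **No ZPD half-weight.** Conventional one-sided FTIR halves the first
  (zero-path-difference) sample, which is the right limit for continuous
  spectra. In the discrete model the unweighted DFT is the exact inverse
  and the half-weight would only introduce ~0.4° RMS of avoidable error,
  so the default applies no sample weighting. A half-Hann apodization is
  available (`apodization = "hann"`) but off by default, as windowing is
  unnecessary in the commensurate configuration and distorts phase.

The experimentally quoted nominal resolution of 35 cm$^{-1}$ corresponds
to a quarter of the default travel and is available as
`default_positions(128, 1/4480)`; the reconstruction metadata then reports
35 cm$^{-1}$. It is *not* the default because the one-sided instrument
line shape at that travel distorts 40–60 cm$^{-1}$-wide absorptive
features by several degrees, which would dominate every downstream
fidelity measurement; with the longer default travel the package isolates
the effects the protocol is designed to control. This is the main point
at which the simulation idealizes the instrument.

Path drift enters the normalized phase as $\Delta\phi = 360\,\nu\,\delta$
degrees ($\nu$ in cm$^{-1}$, $\delta$ in cm): 100 nm of drift offsets the
phase at 1660 cm$^{-1}$ by about 6°, and keeping offsets below 1° at
1400 cm$^{-1}$ requires ~20 nm path stability
(`phase_offset_from_path_drift()`, `path_drift_for_offset()`). Across one
350 cm$^{-1}$ band the offset is constant only to within the ramp
$360 \cdot \mathrm{bandwidth} \cdot \delta$ (~1.3° for 100 nm), which
bounds the error of the constant-offset correction model below.

## Synthetic scenes

Material responses are sums of Lorentzian oscillators over a complex
background,
$\sigma(\omega) = b + \sum_j s_j/(\omega_j^2 - \omega^2 - i\,\gamma_j\omega)$,
with band positions taken from the standard vibrational assignments of the
emulated materials (acrylic copolymer: C=O 1740, ester C–O 1155; fluorine
copolymer: CF$_2$ 1195; polystyrene: weak aromatic bands; keratin: amide
I/II 1660/1550; melanin: 1290, 1454, 1563, 1638 cm$^{-1}$). Oscillator
strengths are set so peak phases fall in the 5–20° range typical of
nano-FTIR phase spectra of organics; absolute peak heights of the real
reference materials are not published, so these are plausible rather than
calibrated values.

**Mixing is defined on phase spectra.** A probed volume containing two
materials is modelled as a convex combination of the *normalized phase
spectra* (and, separately, of the amplitudes), not of the complex
responses. The phase of a sum of complex responses is not the sum of
phases, so this is a modelling choice: it matches the empirical finding
that mixed-volume nano-FTIR spectra behave as linear superpositions of the
pure-component spectra, and it makes the linear-unmixing ground truth
exact by construction. The pixel's complex response handed to the
interferometer model is then $A_{\mathrm{mix}} e^{i\phi_{\mathrm{mix}}}$.

The blend scene (default 62 × 82 px at 30 nm) contains an acrylic
background, elliptical fluoropolymer clusters probed as vertical FP+AC
mixtures (FP share drawn once per scene from 0.70–0.85), polystyrene
disks, and two kinds of 2-px rims: *interface* rims (lateral AC/FP
mixtures, FP share 0.35–0.55) and *interaction* rims carrying a distinct
component in which the CF$_2$ band has shifted 1195 → 1155 cm$^{-1}$ onto
an enhanced ester band (20° peak) while the C=O contribution is reduced.
Because the interaction rim is its own component rather than a weight
rule, it is provably not a superposition of the pure references (noiseless
unmixing misfit ≈ 2.4° RMS), whereas every type-(ii) pixel is one exactly.
The hair scene contains featureless resin, keratin cortex, a ~300 nm
melanin granule with a 2-px mixed rim, and a ~200 nm disk probed as a
50/50 vertical melanin/keratin mixture. Geometry (ellipse axes, disk
radii, rim width ≈ 2 px) is drawn from seeded uniform ranges; scenes are
bit-reproducible given the seed. For scenes much smaller than the default
the geometry ranges shrink proportionally so all five region types still
fit.

What the generator does **not** emulate: tip–sample near-field
electrodynamics and demodulation harmonics (the demodulation order $n=3$
is carried as metadata only), topography–phase crosstalk, detector
nonlinearity, laser repetition structure, amplitude-channel analysis, and
any point-by-point reproduction of the published measured spectra. A green
test therefore establishes the correctness of the *processing chain* under
the stated disturbance models, not instrument realism.

## Acquisition protocol

Lines run parallel to the y axis (a line is one image column; pixels
within a line are fast). Each line begins with a reference spectrum on
clean silicon, modelled as a virtual measurement adjacent to the window,
and the line's spectra are normalized against it (`normalize_line()`:
amplitude ratio, wrapped phase difference; the reference itself maps to
$s \equiv 1, \phi \equiv 0$ at machine precision). Interferometer drift is
piecewise constant per line and applied to sample pixels only — the
physical drift accumulates between the reference and sample acquisitions —
so it survives normalization as the per-band offsets the stitching stage
must correct. Per band, the offset magnitude is drawn from ±115 nm plus a
3 nm/line random walk, so two bands can be offset against each other by up
to ~12°.

Stage drift follows a linear rate (default 0.07/0.05 nm s$^{-1}$) plus a
slow sinusoid (15/10 nm, 40 min period): negligible within one two-line
block (~17 nm < one 30 nm pixel) but tens of pixels over an hours-long
scan, which is exactly the regime that makes block repositioning
necessary. With `reposition = TRUE` the scan pauses after each block of
`m` lines (default 2), renders a topography image (component height map
plus 2 nm roughness noise), estimates the accumulated offset against the
initial topography by FFT cross-correlation with parabolic sub-pixel
refinement (`estimate_stage_drift()`), repositions, and logs the
correction. Scene sampling under drift is nearest-neighbour — the
protocol's own claim is only that drift stays below the spatial
resolution, so sub-pixel drift must not be hidden by interpolation. A
consequence worth noting: pixels of 2-px-wide rims can still record a
neighbouring region's spectrum when the residual displacement rounds to
±1 px; analyses that need pixel-pure spectra should use interior pixels or
neighbourhood averages, as the acceptance tests do.

Acquisition time follows
$n_\mathrm{bands}(n_\mathrm{spectra} \cdot t_\mathrm{spectrum} +
\mathrm{overhead})/3600$; overhead is an argument rather than a constant
because the published total (7.4 h) is consistent with the rounded
per-cube time (2.3 h) plus just under 10 min repositioning per cube.

## Stitching

Offsets between bands are estimated per pixel as the circular mean of the
wrapped phase differences over the spectral overlap of the band supports
(support = envelope ≥ 20% of its maximum; overlaps ≈ 60–70 cm$^{-1}$
wide). Circular averaging keeps the estimate correct near ±180°. Bands I
and III are shifted by constants to match band II; the constant-offset
model is retained even though path drift implies a shallow ramp, with the
ramp bound above asserted in the tests. Weight functions $F^k$ are 1 on
each exclusive support, ramp linearly across each overlap and form an
exact partition of unity on the union; linear (rather than cosine) ramps
are the simplest choice consistent with the published smooth transitions,
and the difference is below the noise. A configuration where all three
supports share a frequency is rejected. The stitched phase
$\phi = \sum_k F^k \phi^k$ is cropped to the union (~1000–1900 cm$^{-1}$).

Baseline correction subtracts, per pixel, the straight line through the
phase values at two anchor frequencies read by linear interpolation
(defaults 1030 and 1870 cm$^{-1}$: just inside the stitched range, away
from all fixture peaks). The corrected spectrum vanishes exactly at the
anchors and the operation is idempotent. Because the line is anchored at
measured (noisy) values, points *outside* the anchor interval carry
extrapolated baseline noise; quantitative per-pixel analyses in the
package therefore default to the anchor interval.

## Multivariate analysis

Distance maps are per-pixel Euclidean distances to a reference phase
spectrum; composite maps convert each distance map to an intensity with
the monotone decreasing scaling $1 - (D - D_{2\%})/(D_{98\%} - D_{2\%})$
(percentile-clipped), so high colour intensity means high similarity, and
sum the hue-weighted channels — pixels far from every reference come out
black, pixels equally close to a red and a blue reference purple.

The inter-spectral distance for clustering is the D-value
$D = (1 - r)\cdot 1000$ with $r$ the Pearson correlation over the analysis
range (default 1000–1850 cm$^{-1}$) — the standard measure of IR
cluster imaging, bounded in [0, 2000] and invariant to affine rescaling of
either spectrum. The reference software behind the published analysis does
not print its formula, so this standard definition is fixed here.
Agglomeration uses Ward's method applied to the D-value matrix directly
via the Lance–Williams update (`stats::hclust(method = "ward.D")`), the
tree is cut at K clusters and labels are renumbered by descending cluster
size (ties by lowest pixel index), making the segmentation deterministic
given the cube. Per-cluster statistics are per-frequency means and
population standard deviations. No optimal-K selection is attempted.

Unmixing fits $\phi \approx \sum_i c_i\,\phi_{\mathrm{ref},i} + c_0$ by
least squares with non-negative coefficients (a self-contained
Lawson–Hanson active-set solver; the offset term is free because baseline
correction can leave small constants) and reports coefficients, residual
RMS and $R^2$; nearly collinear references are flagged but still fitted.
`superposition_test()` declares a spectrum a linear superposition iff its
residual RMS is at or below a threshold, with 3× the median residual of
known-pure pixels as the recommended, documented default.

## Degenerate inputs and tie-breaks

Flat topography (registration), zero-variance spectra (D-value), empty
overlaps, anchors outside range, references vanishing on the band support,
and drift beyond the scene margin all raise typed errors rather than
propagate NaNs. Cross-correlation ties resolve to the first maximum;
cluster-size ties to the lowest member pixel index; the parabolic
sub-pixel refinement degenerates to the integer peak when curvature
vanishes.

## Known limitations

* The instrument idealizations listed under the forward model; in
  particular the default travel removes the finite-resolution line-shape
  distortion a 35 cm$^{-1}$ instrument would show.
* Phase mixing is exact by construction; real mixed volumes superpose
  fields, not phases, so the unmixing results quantify the analysis chain,
  not near-field physics.
* Per-pixel classification of 2-px-wide rims is limited by the
  nearest-neighbour sampling under residual (< 1 px) stage drift, as
  discussed above.
* Band cubes share a single global frequency grid; stitching more than
  three bands, or bands whose supports triple-overlap, is out of scope.
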
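---
title: "Spectral-shift fluorescence microscopy: models and design choices"
author: "ssfm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-shift fluorescence microscopy: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfm)
```

## The measurement model

A spectral-shift fluorescence microscope raster-scans a stained specimen
with a 532 nm laser and records, for every pixel `(i, j)` of an `m x n`
grid, a full fluorescence emission spectrum through a grating
spectrometer (0.4 nm resolution). The default scan geometry is 60 x 30 =
1800 pixels of 16 μm. The image information lives in three co-registered
matrices: the peak signal intensity `[I_ij]`, the peak emission
wavelength `[λ_ij]`, and the fluorophore concentration `[c_ij]` derived
from `[λ_ij]`.

The physics the package models is the behaviour of rhodamine 6G (Rd6G)
in tissue. Rd6G emits over roughly 540–600 nm. Its peak emission
red-shifts with local concentration (reabsorption at high density) and
blue-shifts when the active fluorophore population is depleted —
which is exactly what happens when Rd6G conjugates to the mitochondria of
malignant cells. The resulting characteristic peak positions are 550 nm
(melanoma), 555 nm (BCC), 563 nm (SCC), ~570 nm (normal tissue) and
>575 nm (benign nevus, whose extreme redshift is driven by melanin
autofluorescence rather than Rd6G density).

### Intensity versus concentration

Signal intensity follows a quenched linear model

$$ I(c) = a\,c\,e^{-c/\kappa}, $$

which rises to a single maximum at \(c=\kappa\) and falls beyond it. The
package default is \(\kappa = 30/\ln 4 \approx 21.64\) μM, the unique
value for which \(I(10) = I(40)\) holds exactly — the canonical
illustration of why intensity alone cannot determine concentration
(`concentration_candidates_from_intensity()` exposes the two-valued
inverse). Amplitude `a` defaults to 1 (arbitrary detector units; the
instrument's absolute scale is not specified anywhere, so no particular
unit is pretended).

### Wavelength versus concentration

The calibration is a strictly monotone anchor set,
(2, 550), (8, 555), (10, 563), (16, 570) μM/nm, interpolated by a
monotone piecewise-cubic (PCHIP) curve; a piecewise-linear mode is kept
for cross-checks. The inverse `wavelength_to_concentration()` is **not**
a second interpolant: it is computed by bracketed root-finding
(`uniroot`, tolerance ~1e-12) on the forward curve, which makes the round
trip `c → λ → c` exact to better than 1e-9 relative — a property a pair
of independent interpolants would not have. The nevus pairing
(12 μM, 581 nm) is deliberately excluded from the anchors: including it
would claim that melanin autofluorescence sits on the Rd6G density curve,
and it would not change monotonicity anyway. Nevus concentrations are
reported by class-table lookup instead, and nevus pixels fall outside the
calibration span by design (they become missing unless extrapolation is
requested).

The formal calibration operator (`k_operator()`) has two supported
forms: the bare-fluorophore identity-scalar case `c = k·λ`, and the
stained-tissue case where the per-pixel monotone table plays the role of
the diagonal characteristic matrix. A non-diagonal operator (spatial
cross-talk between pixels) has no defined construction and is rejected
explicitly.

## The forward simulator

`simulate_cube()` is the package's study-condition generator; its
defaults are the instrument's stated conditions and are not tuned per
experiment:

* **Class table** (`default_class_table()`): centers 550/555/563/570/581
  nm; spreads 2/4/3.3/4.1/14.8 nm (the per-class scatter statistics);
  typical concentrations 2/8/10/16/12 μM. The nevus spread is quoted in
  several places as ~10, ~12 and 14.8 nm; 14.8 nm is adopted because it
  is the data-scattering statistic the summary `width_nm` column
  estimates. The 12-vs-16 μM assignment between nevus and normal follows
  from normal tissue having the densest active fluorophore content.
* **Per-pixel peak wavelength**: Uniform(center ± spread/2), so that the
  recovered range (max − min) of a class is an almost unbiased estimator
  of the spread — the expected range of a uniform sample of size n is
  spread·(n−1)/(n+1), a 0.1% bias at n = 1800. A Gaussian alternative
  (sd = spread/4) sits behind `spread_dist = "gaussian"`.
* **Lineshape**: Gaussian with σ = 6 nm, chosen so a 550–581 nm peak
  range produces a visible envelope over roughly 540–600 nm. No value is
  stated by the instrument description; this is a package choice.
* **Grid**: 500–650 nm at 0.4 nm (376 samples) — the spectrometer
  resolution restricted to the emission region.
* **Noise**: additive Gaussian, or Rician as the magnitude of a complex
  Gaussian perturbation (the correct model for magnitude spectra);
  `relative = TRUE` scales σ by each pixel's noise-free amplitude for
  "percent of amplitude" conditions.
* **Dichroic cutoff**: the response at and below 535 nm is zeroed (laser
  line 532 nm plus margin).
* **Determinism**: R's default Mersenne-Twister; all peak wavelengths
  are drawn first, then the noise matrix, so a seed fully determines a
  cube.

What the simulator does **not** emulate: optical point-spread overlap
between pixels, photobleaching, depth sectioning, autofluorescence
baselines other than the nevus center shift, and specimen-level
morphology. Passing tests therefore demonstrate correctness of the
algorithmic pipeline under the stated statistical model, not clinical
performance on real tissue.

## Preprocessing

Order is fixed — mask, debias, smooth — and the configuration rejects any
other order, because the stages do not commute: masking first keeps
smoothing from leaking laser energy into the emission band, and the
Rician correction must see raw magnitudes, not smoothed ones.

* **Masking** zeroes wavelengths ≤ the 535 nm dichroic cutoff.
* **Rician debias** replaces each magnitude M by
  \(\sqrt{\max(M^2 - 2\sigma^2, 0)}\) (the Rice distribution's second
  moment is \(A^2 + 2\sigma^2\)); σ = 0 disables it.
* **Smoothing** is discrete Gaussian convolution with σ given in nm and
  converted using the grid's *nominal* step (recomputing the step from
  floating-point wavelength differences can change the truncation
  half-width by one sample and was rejected for that reason). The kernel
  is truncated at 4σ, normalized to unit mass, with symmetric-reflection
  boundaries; the default σ is 0.8 nm (two grid steps). The spatial
  counterpart is the optional 3×3 modal label filter in classification.

## Peak detection

The per-pixel peak is the global argmax over the unmasked band (ties go
to the lower wavelength, for determinism), refined by a quadratic fit to
the log-intensity at the argmax and its two neighbours. For a Gaussian
lineshape the log is exactly quadratic, so noise-free recovery is exact
to machine precision — and remains so after Gaussian smoothing, since a
Gaussian convolved with a Gaussian is (to discretization accuracy)
Gaussian. The fit falls back to the raw grid wavelength when the parabola
is non-concave, a neighbour is zero, or the argmax sits at a band edge.
Pixels with fewer than three nonzero samples become missing (`NA`), are
listed in a report, and abort the run if they exceed 10% of the scan
(configurable).

Two reference constants coexist for normal tissue: the classification
center 570 nm, and the 569 nm *reporting convention* used for blue-shift
statements, under which the class triple against healthy tissue is
exactly 19/14/6 nm and the normal-vs-laser shift is 37 nm. The two
cannot be reconciled against a 532 nm laser line (570 − 532 = 38), so
both are kept as named, configurable constants rather than silently
averaged.

## Classification and summaries

Bands are closed-open intervals covering [548, 588): boundaries between
class centers are midpoints (553, 559, 566 nm), and the normal/nevus
boundary is 575.5 nm. These are editorial decisions — the source material
gives class ranges, not decision boundaries — and are fully overridable
via JSON. With the default table, only the nevus distribution (spread
14.8 nm around 581 nm) crosses a boundary, so noise-free phantoms
classify perfectly except for the documented nevus/normal overlap.

The class summary reports count, fraction, mean/min/max wavelength,
width (max − min), modal shift and the table concentration. The *modal
shift* is computed as the median per-pixel shift rounded to the nearest
nanometre rather than the arg-max of a 1-nm histogram: for the
generator's flat-topped uniform distributions a histogram mode has
near-ties across adjacent bins and is not a stable statistic, while
median and mode coincide for unimodal symmetric distributions. This was
settled at design time as the robust estimator of a class's
characteristic shift.

## Rendering

The 548–588 nm window maps linearly (sequential order, not perceptually
uniform) onto a five-stop blue→green→orange→red→dark-red ramp anchored
at the class centers, matching the verbal color assignments: melanoma
blue-dominant, BCC green, SCC yellow/orange, normal vivid red, nevus
dark red. The instrument's original per-bin RGB table is not published,
so only channel dominance — never exact RGB values — is asserted
anywhere. Concentration micrographs are rendered by first mapping
concentration back to wavelength through the calibration, so the
concentration and shift images share spectral features by construction.
Missing pixels render black; images are 8-bit PNG/TIFF and round-trip
losslessly.

## File formats and numerical choices

* Cube dialects: long CSV (`i,j,wavelength_nm,intensity`, 1-based) and a
  hierarchical JSON container (`grid/wavelength_nm`, `cube/intensity`,
  `attrs`). A missing pixel of a declared scan is an error naming the
  pixel, never a silent fill. Pixel indexing is 1-based internally
  (native to R matrices); the phantom-file dialect keeps its documented
  0-based half-open rectangles and is converted on read.
* Map export: `i,j,value` CSV, and float32 TIFF normalized to [0.1, 0.9]
  with a JSON sidecar carrying the affine range (the TIFF writer only
  defines storage inside [0, 1]); missing encodes as 0.
* Negative intensities (baseline-subtracted data) are clipped to zero on
  ingest with a logged count, not rejected.
* Degenerate inputs: all-zero spectra are report-coded
  (`empty_spectrum`) and become missing pixels; non-finite data and
  non-monotone grids are hard validation errors.

## Problem sizes used in the test suite

Deterministic worked examples run on the full 60 × 30 default scan
(seconds each). Stochastic properties use 1000-pixel scans for the
Rician recovery bound (median |λ̂ − λ*| ≤ 0.2 nm at σ = 2% amplitude),
1800 pixels × 10 seeds for the nevus width recovery, and 100–200
random draws for oracle-equivalence and round-trip properties. These
sizes were chosen as the package's own desk-scale study conditions:
large enough that range statistics have sub-percent bias, small enough
that the whole suite runs in well under a minute per file.

## Known limitations

* The simulator's statistical model is the package's definition of the
  instrument; no deposited instrument data exists to validate against.
* Classification is pure interval lookup; no spatial prior beyond the
  optional 3×3 modal filter, and no supervised classifier.
* The non-diagonal calibration operator (pixel cross-talk) is
  unsupported by design.
* Multi-peak spectra (overlapping fluorophores) are not decomposed; the
  global argmax wins.
* Nevus/normal separation is intrinsically imperfect: the nevus spread
  crosses the 575.5 nm boundary, a property of the tissue classes, not
  of the implementation.
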
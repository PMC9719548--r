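# ssfm — spectral-shift fluorescence microscopy image analysis

`ssfm` processes raster-scanned per-pixel fluorescence spectra from
spectral-shift fluorescence microscopy (SSFM) of rhodamine-6G (Rd6G)
stained skin tissue. In SSFM each scan pixel `(i, j)` yields a full
emission spectrum, and micrographs are formed not only from the signal
intensity but from the **peak emission wavelength**, which shifts with the
tissue state: heavy Rd6G conjugation to the mitochondria of malignant
cells depletes the active fluorophore population and blue-shifts the
emission, while dense active fluorophore in healthy tissue red-shifts it
through reabsorption. The package is for researchers building or
evaluating spectral-shift imaging pipelines, and for anyone who needs a
testable, fully synthetic stand-in for such an instrument.

## The method

From a spectral cube (an `m x n x W` array of intensities over a shared
wavelength grid) the pipeline produces three co-registered matrices,

- `[I_ij]` — peak signal intensity (a.u.),
- `[λ_ij]` — peak emission wavelength (nm), refined below the 0.4 nm grid
  resolution by a log-quadratic 3-point fit (exact for Gaussian
  lineshapes),
- `[c_ij]` — Rd6G concentration (μM), obtained from `[λ_ij]` through a
  monotone calibration with anchors at the class pairings
  (2, 550), (8, 555), (10, 563), (16, 570) μM/nm,

plus the spectral-shift map `Δλ_ij = λ_ij − λ_L` against the 532 nm
laser line. Concentration is deliberately derived from wavelength, not
intensity: the quenched intensity model `I(c) = a·c·exp(−c/κ)` with
`κ = 30/ln 4 ≈ 21.64 μM` is non-monotone, so one intensity generally
corresponds to two concentrations (e.g. 10 and 40 μM give equal signal),
while the wavelength–concentration relation is monotone and invertible.

Pixels are then classified by spectral band — melanoma [548, 553), BCC
[553, 559), SCC [559, 566), normal [566, 575.5), nevus [575.5, 588) nm —
and rendered as false-color micrographs (intensity, shift, concentration,
labels). Characteristic shifts versus the laser line are 18 nm
(melanoma), 23 nm (BCC), 31 nm (SCC), 37 nm (normal) and 49 nm (nevus);
equivalently, blue shifts against healthy tissue of 19, 14 and 6 nm.

A forward simulator (`simulate_cube()`) generates labeled tissue phantoms
with class-specific Gaussian emission lineshapes, concentration-dependent
amplitude with quenching, additive Gaussian or Rician detector noise, and
the dichroic cutoff of the real instrument, so every stage of the pipeline
is testable at desk scale without instrument data.

## Worked example

```r
library(ssfm)

ph <- phantom_spec(m = 60, n = 30, background = "normal",
  regions = list(list(i0 = 1,  i1 = 30, j0 = 1, j1 = 15, label = "melanoma"),
                 list(i0 = 31, i1 = 60, j0 = 1, j1 = 15, label = "scc")))
cfg   <- pipeline_config(seed = 42)
paths <- ssfm_simulate(ph, cfg, "runs/sim")     # cube + ground truth
res   <- ssfm_process(paths$cube, cfg, "runs/out")
print(res$summary, digits = 4)
```

```
         label count fraction mean_nm min_nm max_nm width_nm modal_shift_nm typ_conc_uM
1     melanoma   450     0.25   550.0  549.0  551.0    1.978             18           2
2          bcc     0     0.00      NA     NA     NA       NA             NA           8
3          scc   450     0.25   563.0  561.4  564.6    3.288             31          10
4       normal   900     0.50   569.9  568.0  572.0    4.092             38          16
5        nevus     0     0.00      NA     NA     NA       NA             NA          12
6 unclassified     0     0.00      NA     NA     NA       NA             NA          NA
```

The melanoma region is recovered at its characteristic 18 nm shift
(550 nm peak) and 2 μM, the SCC region at 31 nm (563 nm) and 10 μM, and
the normal background at its 570 nm classification center (38 nm against
the laser line; the 569 nm reporting convention yields the printed 37 nm
figure — both constants are configurable). The recovered `width_nm`
column reproduces each class's spectral scatter (2, 3.3, 4.1 nm here).
`runs/out/` now holds the four maps as CSV, the per-pixel scatter table,
four rendered PNG micrographs (melanoma renders blue-dominant, SCC
yellow/orange, normal vivid red) and a run manifest with the seed and the
resolved configuration.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/ssfm.R simulate --phantom phantom.json --seed 42 --out runs/sim
Rscript inst/scripts/ssfm.R process  --cube runs/sim/cube.json --out runs/out --verbose
Rscript inst/scripts/ssfm.R report   --summary runs/out/class_summary.csv
```

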
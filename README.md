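# axisim

Simulation and super-resolution reconstruction for **axial-interference
speckle illumination microscopy**: a widefield fluorescence scheme in which
a plain mirror ~100 µm above the sample reflects the coherent speckle
excitation back through it, so that counter-propagating components
interfere and compress the illumination's axial structure to a
standing-wave period of λ/(2n) ≈ 183.5 nm. Temporal cumulant analysis of
the resulting intensity fluctuations (SOFI/SACD style) then yields
near-isotropic 3-D super-resolution from an otherwise ordinary microscope.

The package is aimed at method developers who want to exercise, probe and
quantify this reconstruction pipeline end to end **without a microscope**:
every experiment runs on synthetic data with known ground truth.

It provides:

* **Optics simulator** — angular-spectrum synthesis of coherent speckle
  with and without the back-reflecting mirror (reflectance, gap and tilt
  configurable), scalar Born–Wolf detection PSFs, and the *effective
  speckle PSF* (the autocorrelation of illumination × detection PSF, the
  resolution-bearing kernel of fluctuation imaging).
* **Forward model** — bead / hollow-shell / filament / moving-particle
  phantoms rendered into speckle-illuminated EMCCD frames (Poisson photons,
  EM-gain excess noise, read noise, offset, optional drift), scanned in z
  like a nanostage acquisition; bitwise-reproducible per seed.
* **Preprocessing** — sub-pixel phase-correlation drift registration,
  refractive-index axial rescaling, chromatic z-offset channel alignment.
* **Reconstruction** — per-frame Richardson–Lucy (RL) deconvolution, DSI
  weighting W(r) = RMS over time, reweighting `F'(r,t) = F_RL(r,t) × W(r)`
  with square-root brightness linearization, 2× lateral Fourier
  interpolation, 2nd/3rd-order temporal cumulants, 3-D RL with an
  FRC-assisted stopping rule, n-th-root brightness linearization and
  z-intensity flattening.
* **Metrics** — SSIM, image-decorrelation resolution (with a 22.5° axial
  sector mode), bead FWHM, the resolution isotropy ratio (RIR), and simple
  particle tracking.
* **Pipeline driver** — `run_pipeline()` plus a thin CLI
  (`inst/scripts/axis-sim`) with `simulate | preprocess | reconstruct |
  evaluate | demo` subcommands, YAML configs, TIFF/CSV/JSON artifacts and
  an MD5-checksummed manifest.

## Core quantities

For a speckle illumination intensity `S(r)` and detection PSF `U(r)`, the
effective speckle PSF is `AC[S·U]`; the mirror compresses its axial FWHM
several-fold. Per pixel and z layer the reconstruction computes

```
W(r)    = sqrt( mean_t F_RL(r,t)^2 )          # DSI weight (quasi-confocal)
F'(r,t) = sqrt( F_RL(r,t) · W(r) )            # reweighted, linear brightness
C2(r)   = mean_t[ δF'(r,t) δF'(r,t+τ) ]       # δ = mean-subtracted; τ = 0
C3(r)   = mean_t[ δF'(t) δF'(t+τ) δF'(t+2τ) ]
```

followed by 3-D RL deconvolution of the stacked cumulant volume.

## Worked example

```r
library(axisim)

# Axial confinement of the effective speckle PSF by the mirror
# (10 diffuser realizations; the acceptance run uses 50)
ratio <- effective_psf_axial_ratio(n_seeds = 10, seed = 1,
                                   grid = c(96L, 64L, 64L))
round(as.numeric(ratio), 2)
#> [1] 7.28
round(attr(ratio, "fwhm_nm"), 1)
#> mirror_off  mirror_on
#>      725.1       99.6

# Frame-budget fidelity: DSI from 50 frames vs a 500-frame reference
median(dsi_frame_budget_ssim(seeds = 1, n_seeds = 3))
#> [1] 0.998

# Resolution isotropy report
resolution_report(108.5, 140.1)
#> resolution (decorrelation): lateral 108.5 nm, axial 140.1 nm, RIR 1.29
```

The first block says the mirror shrinks the axial footprint of the
fluctuation kernel from ~725 nm to ~100 nm (a 7× confinement) under the
reference conditions (488 nm excitation, NA 1.49 oil objective,
illumination NA 0.7, water sample, mirror 100 µm above the sample at
reflectance 0.97). The second says 50 speckle frames per layer already
reproduce the 500-frame DSI image almost perfectly (SSIM 0.998) on a bead
sample. The third computes the axial/lateral resolution isotropy ratio of
a final reconstruction: 1.29, i.e. near-isotropic.

An end-to-end run on a filament phantom:

```sh
Rscript inst/scripts/axis-sim demo --seed 2 --out demo-run
cat demo-run/resolution.csv
#> "metric","value"
#> "lateral_resolution_nm",95.2380952380952
#> "axial_resolution_nm",52.0833333333333
#> "rir",0.546875
#> "dl_lateral_resolution_nm",250
#> "dl_axial_resolution_nm",53.1914893617021
```

The reconstruction's lateral decorrelation resolution (95 nm) improves
2.6× on the diffraction-limited DSI baseline (250 nm). The axial estimates
of this miniature demo saturate near the axial sampling band edge
(2 × 25 nm) and should be read as "finer than measurable at this scan
range", not as a resolution claim; the bead-FWHM acceptance study below is
the meaningful axial quantification.

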
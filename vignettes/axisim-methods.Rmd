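---
title: "Mirror-assisted speckle illumination microscopy: model, reconstruction and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-assisted speckle illumination microscopy: model, reconstruction and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The imaging problem

Widefield fluorescence microscopy resolves ~250 nm laterally but only
600–800 nm axially: the detection point spread function (PSF) is strongly
elongated along the optical axis. Super-resolution methods that exploit
temporal intensity fluctuations — dynamic speckle illumination (DSI) and
SOFI/SACD cumulant analysis — inherit this anisotropy, because the
fluctuation-bearing illumination itself decorrelates slowly along z.

`axisim` models and reconstructs a minimal-hardware remedy: a plain mirror
placed ~100 µm above the sample reflects the coherent speckle excitation
back through the sample. Each downward-propagating plane-wave component
interferes with its upward-propagating reflection, imprinting a
standing-wave structure of period

$$\Delta z = \frac{\lambda_{exc}}{2 n_{sample}} \approx
  \frac{488}{2 \times 1.33} \approx 183.5\ \mathrm{nm}$$

on every speckle grain. The axial autocorrelation of the illumination —
and with it the *effective speckle PSF*, the resolution-bearing kernel of
fluctuation imaging — is thereby compressed from several hundred nanometres
to a central lobe of well under 200 nm, while the lateral speckle statistics
are nearly unchanged. Because the interference survives mirror tilts of
several degrees (each speckle component simply acquires a transverse
momentum offset), no interferometric alignment is needed.

# The optical model

## Coherent speckle synthesis (`sample_pupil`, `synthesize_speckle`)

The excitation field is synthesized with a scalar angular-spectrum model.
A rotating ground-glass diffuser is represented by circular-Gaussian
complex amplitudes on the objective's back focal plane, non-zero inside a
disk of radius $\mathrm{NA}_{ill} k_0$ (fully developed speckle). Each
plane-wave component propagates with
$k_z = \sqrt{(n k_0)^2 - k_\perp^2}$; components with
$k_\perp > n_{sample} k_0$ are evanescent in the sample medium and are
dropped (their count is logged). With the mirror enabled, each z plane
receives the coherent sum

$$E(z) = \mathcal{F}^{-1}\!\left[ A(k_\perp) e^{i k_z z}
  + r\, A_{tilt}(k_\perp) e^{i k_z (2d - z)} \right],$$

where $d$ is the mirror height, $r$ the scalar amplitude reflectance
(default 0.97, silver), and tilt is a transverse frequency shift of the
reflected pupil by $2 n k_0 \sin\theta$ (small-angle model, valid to ~15°).
This replaces a full-vector electromagnetic treatment; scalar coherent
superposition is sufficient to reproduce the speckle statistics that drive
the reconstruction, and full temporal coherence is assumed (the ~100 µm
round trip is far shorter than the laser coherence length). Polarization,
metal dispersion and interface aberrations are not modelled.

Key tunable parameters (defaults in `optical_config()`):

* `wavelength_exc` = 488 nm, `wavelength_em` = 520 nm;
* `numerical_aperture` = 1.49 (oil, $n_{imm}$ = 1.518), `n_sample` = 1.33
  (aqueous);
* `lateral_spacing` = 40 nm, `axial_spacing` = 20 nm for PSF studies
  (80/25 nm for acquisition simulations) — the lateral spacing must satisfy
  the speckle Nyquist bound $\lambda_{exc}/(2\,\mathrm{NA})$;
* `illumination_na` = 0.7: the effective NA of the diffused beam at the
  pupil. This number controls the axial correlation length of the random
  speckle and is not derivable from first principles here (the beam does
  not fill a TIRF objective's full aperture, and supercritical components
  cannot propagate in water). It was calibrated once so that the simulated
  *mirror-free* effective speckle PSF has an axial FWHM of ~0.7 µm,
  matching the reference system's measured baseline; with a fully-filled
  NA-1.49 pupil the simulated baseline would be an unrealistically short
  ~450 nm. All other results are measured, not tuned, downstream of this
  single choice.

## Detection PSF (`detection_psf`)

The detection PSF is the scalar Born–Wolf diffraction integral
$h(r,z) \propto \left| \int_0^1 J_0(k\,\mathrm{NA}\,\rho\,r)
e^{-i k z \rho^2 \mathrm{NA}^2 / 2n}\, \rho\, d\rho \right|^2$
evaluated by midpoint quadrature (120 radial nodes; the Bessel matrix is
reused across defocus planes) and normalized to unit sum. At the default
emission settings its lateral FWHM is within a few percent of the Airy
width $0.51 \lambda/\mathrm{NA} \approx 178$ nm and its axial FWHM is
~630 nm. Aberration-free imaging is assumed; see *Limitations*.

## Effective speckle PSF (`effective_speckle_psf`, `fwhm`)

The effective speckle PSF is the (periodic, Wiener–Khinchin) 3-D
autocorrelation of the product of one speckle realization and the detection
PSF, peak-normalized with zero lag at the centre voxel. Axial profiles of
the mirror-on kernel carry interference sidelobes, so `fwhm()` measures the
central lobe against a *local* baseline: walking outward from the peak, the
first genuine valley (a rebound larger than 5% of the peak range) defines
the baseline; monotone profiles fall back to their endpoint value. Noisy
bead profiles use a larger rebound tolerance and a 3-sample moving average
(`bead_fwhm_3d(smooth = 3)`).

At the reference conditions the median axial FWHM over 50 diffuser
realizations is ~690 nm without the mirror and ~105 nm with it — a
confinement ratio of ~6 (the package's first acceptance check requires
≥ 4). The lateral FWHM changes by well under 20%, and a 10° mirror tilt
leaves the axial confinement within 25% of the aligned case.

# The forward (acquisition) model

Phantoms are non-negative density grids: spheres with analytically
normalized mass (`make_beads`), spherical shells with empty lumina
(`make_hollow_shells`), Gaussian-cross-section random-walk tubes with
constant linear density (`make_filaments`), and constant-speed moving
point particles (`make_moving_particles`, default speeds 60–100 nm/s,
bracketing reported lysosome velocities of ~79–88 nm/s).

A camera frame is the focal-plane readout of
(phantom × illumination) ⊛ detection-PSF, computed with FFTs
(periodic boundaries) over all phantom planes, so out-of-focus light is
fully included — essential for testing optical sectioning. The EMCCD model
applies Poisson photon statistics, a Gamma-cascade EM gain (doubling the
shot-noise variance) or a fixed gain, Gaussian read noise and an offset.
The default photon budget is 500 photons per frame at the brightest
in-focus voxel with read noise of 2 counts — bright enough that a 50-frame
cumulant analysis is feasible, dim enough that noise matters; the
reference system's budget is not published, so this is an engineering
choice fixed before any acceptance measurement.

`acquire_stack()` scans z in nanostage steps equal to the phantom's axial
spacing (25 nm for bead studies), records `frames_per_layer` frames per
layer (50 for fixed samples, 100 for live, per the reference acquisition
protocol) under fully independent speckle realizations — the
rotating-diffuser model; frame-to-frame illumination correlation is below
0.05 — and can inject linear lateral drift. Every pupil and noise draw is
seeded deterministically from the master seed, so acquisitions are
bitwise reproducible.

What the generator does *not* emulate: photobleaching, fluorophore
blinking (fluctuations come exclusively from the illumination), chromatic
crosstalk, depth-dependent spherical aberration, and refractive-index
distortion of the z axis (the corrector `axial_rescale()` is provided and
tested on synthetic distortions, but the forward model itself scans true
z). Passing tests therefore demonstrate the *method's* behaviour under
controlled statistics, not instrument-specific artefacts.

# Preprocessing

* `estimate_shift()`/`register_stack()`: phase correlation with 20×
  Fourier-upsampled sub-pixel refinement, two refinement passes against
  the per-layer temporal mean (a drift-smeared first reference is sharpened
  by the second pass). Estimates larger than `max_shift` (default 10 px)
  are rejected as noise failures. Residuals after removing a 0.05 px/frame
  linear drift are below 0.1 px.
* `axial_rescale()`: a single-factor $n_{sample}/n_{imm}$ cubic (Keys)
  resampling of the z axis with amplitude compensation, so integrated
  intensity is conserved to 1%. A depth-dependent variant is out of scope;
  the linear factor is the documented first-order correction.
* `align_channels()`: sub-voxel z shift of one channel by a measured
  chromatic offset (validity range ±2 µm; the reference system's measured
  488/633 offset is below 1 µm).

# Reconstruction

Per z layer (`reconstruct_layer`):

1. per-frame 2-D Richardson–Lucy (RL) deconvolution with the in-focus PSF
   slice, 10 iterations (multiplicative updates, FFT convolutions,
   divisions regularized by $10^{-9} \times$ the image maximum);
2. DSI weight $W(r) = \sqrt{\langle F_{RL}(r,t)^2 \rangle_t}$ (raw RMS;
   a mean-subtracted variant is available via
   `recon_config(mean_subtract_dsi = TRUE)` since the convention is not
   fixed in the literature);
3. reweighting $F'(r,t) = F_{RL}(r,t) \times W(r)$ followed by an
   elementwise square root — the weighting squares the effective
   brightness, the root restores a linear scale;
4. lateral Fourier interpolation by a factor of 2 (zero-padded spectrum,
   even-size Nyquist bins split so band-limited content is reproduced
   exactly; DC preserved);
5. the temporal autocorrelation cumulant at order $n \in \{2, 3\}$ and lag
   $\tau$ (default 0, reducing to central moments): the magnitude feeds
   the next stage, the sign map is kept for diagnostics (negative
   third-order cumulants are physical; their fraction is logged).

The **DL baseline** returned alongside is the plain DSI image — the RMS of
the *raw* frames. The weight map $W(r)$ is computed from the deconvolved
frames, per the reconstruction recipe, but using it as the
"diffraction-limited" reference would already contain deconvolution gain;
the two roles are deliberately separated in the code.

Per volume (`reconstruct_volume`): cumulant slices are stacked and
deconvolved with 3-D RL using the detection PSF resampled to the upsampled
lateral grid. The iteration count is either fixed or chosen by the Fourier
ring correlation (FRC) stopping rule (`select_rl_iterations`): the frame
series is split into odd/even halves, two half-data volumes are built, RL
is checkpointed at candidate counts (default 1–40), and the count
minimizing the FRC resolution (1/7 threshold) between matched
highest-energy slices is returned. Ties at the measurement's band edge —
which always occur for noise-free or point-dominated content, whose
half-images differ only by a scalar — go to the *largest* candidate
(resolution still saturated), other ties to the smallest
(over-deconvolution guard).

Brightness linearization (`brightness_linearize`) applies an extra RL, an
$n$-th root, and optionally a reconvolution with the system PSF. The
reconvolution is **off by default in the volume pipeline**
(`recon_config(linearize_reconvolve = FALSE)`): the detection PSF's
~630 nm axial width vastly exceeds the reconstruction's axial resolution,
so reconvolving with it is a display-smoothing operation that would
surrender nearly all of the axial gain. The root itself is kept — it is
what makes bead brightnesses comparable.

`z_flatten()` divides each slice by a robust gain (mean over pixels above
10% of the slice maximum, 5-slice moving average, unsmoothed for stacks
shorter than the window) and rescales to the original global maximum.

## Resolution-quantification configuration

FWHM measurements on isolated identical beads are made with
`linearize_brightness = FALSE` and `z_flatten = FALSE` and a fixed 40
3-D-RL iterations:

* the $n$-th root is a *photometric* correction; applied to a sharply
  deconvolved point it widens every residual noise bump past the
  half-maximum (the linearized bead reads ~160 nm axial FWHM — consistent
  with the reference system's third-order bead widths — but the DL/recon
  *ratio* is then limited by the simulation's idealized ~630 nm DL
  baseline, not by the reconstruction);
* z-flattening equalizes slice intensities, i.e. it divides an isolated
  bead's own axial profile away — meaningful for extended samples,
  nonsensical for the bead ruler;
* the FRC rule is uninformative for sparse point phantoms (see above), so
  the auto cap (40) is used directly.

Under this configuration the median DL/reconstruction axial FWHM ratio
over 12 beads (two independent 56-layer acquisitions at 50 frames/layer)
is ~6, against an acceptance floor of 5.

# Quantification

* `ssim()`: standard 11×11 Gaussian-window SSIM (σ = 1.5, K₁ = 0.01,
  K₂ = 0.03, dynamic range = joint value range). The 50-vs-500-frame DSI
  frame-budget check yields SSIM ≈ 0.99 on the synthetic bead sample
  (floor: 0.88).
* `decorr_resolution()`: image decorrelation analysis — correlation of the
  spectrum with its phase-normalized copy under 50 cumulative radial masks,
  repeated for 10 log-spaced Gaussian high-pass widths; the cutoff is the
  highest interior-maximum position across curves and the resolution
  $2\,\mathrm{px}/k_c$. Curves whose maximum sits on the noise-dominated
  band edge carry no peak and are flagged indeterminate. Axial mode masks
  the spectrum to a 22.5° full-opening sector about the $k_z$ axis
  (both half-axes) of an xz slice. On volumes, the lateral estimate uses
  the highest-energy xy slice and the axial estimate the highest-energy xz
  slice — the aggregation convention, since the reference does not state
  one.
* `bead_fwhm_3d()`, `resolution_report()`: orthogonal profile FWHMs and
  the resolution isotropy ratio RIR = axial/lateral (1 = isotropic).
* `track_particles()`: threshold + connected components +
  intensity-weighted centroids, greedy nearest-neighbour linking gated at
  500 nm/frame (adequate for sparse particles; globally optimal assignment
  is out of scope), speed = path length / elapsed time. Injected 80 nm/s
  tracks are recovered within 5%.

# Problem sizes and runtime

The test-suite simulations are sized for a single CPU: effective-PSF
statistics on 64×64×96 voxel grids over 50 seeds (~1 min); the bead
sharpening study on 48×48 px × 56 layers × 50 frames, two seeds (~2 min);
the frame-budget SSIM on 64×64 px × 500 frames × 5 seeds (~15 s). These
sizes were chosen as the smallest at which the measured quantities are
stable across seeds; the acquisitions' physical parameters (wavelengths,
NA, z steps, frame counts, mirror geometry) are the reference conditions
throughout.

# Known limitations

* Scalar optics: no polarization, vector high-NA effects, metal
  dispersion, or coherent multiple reflections beyond a single mirror
  branch.
* Aberration-free Born–Wolf detection: experimental DL baselines
  (aberrations, index mismatch) are wider than simulated ones, so
  simulated DL-relative fold changes are conservative for the DL side.
* Periodic (FFT) boundary conditions throughout; phantoms should keep a
  margin from the volume faces.
* i.i.d. speckle frames: a finite diffuser correlation time would lower
  the effective number of independent frames.
* Third-order cumulants from 50 frames are statistically noisy;
  single-bead axial profiles are ragged at the ±30% level, which is why
  bead statistics are reported as medians over beads and seeds.
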
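#' EMCCD noise model
#'
#' @param photons_at_peak expected photons per frame at the brightest voxel
#'   of an in-focus object under mean illumination.
#' @param em_gain electron-multiplying gain (counts per photoelectron).
#' @param read_noise_sd Gaussian read noise (counts).
#' @param offset camera bias (counts).
#' @param excess_noise logical; model the EM register's multiplicative
#'   excess noise (doubles the shot-noise variance, Gamma gain model).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(photons_at_peak = 500, em_gain = 30,
                        read_noise_sd = 2, offset = 100,
                        excess_noise = TRUE) {
  if (photons_at_peak <= 0) stop("photons_at_peak must be > 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  structure(list(photons_at_peak = photons_at_peak, em_gain = em_gain,
                 read_noise_sd = read_noise_sd, offset = offset,
                 excess_noise = isTRUE(excess_noise)),
            class = "noise_model")
}

#' Apply EMCCD noise to an expected-photon image
#'
#' Draws Poisson photoelectrons from the expected photon map, amplifies by
#' the EM gain (as a Gamma cascade when `excess_noise` is on, doubling the
#' shot-noise variance; as a fixed gain otherwise), then adds Gaussian read
#' noise and the camera offset. Output is clipped at zero.
#'
#' @param expected non-negative array of expected photons.
#' @param noise a [noise_model()].
#' @param seed integer seed; identical seeds give identical draws.
#' @return counts array of the same shape.
#' @export
apply_noise <- function(expected, noise, seed) {
  if (any(expected < 0)) stop("expected photon map must be non-negative")
  d <- dim(expected)
  with_seed(seed, {
    n <- stats::rpois(length(expected), as.vector(expected))
    if (noise$excess_noise) {
      counts <- numeric(length(n))
      pos <- n > 0
      counts[pos] <- stats::rgamma(sum(pos), shape = n[pos],
                                   scale = noise$em_gain)
    } else {
      counts <- n * noise$em_gain
    }
    counts <- counts + stats::rnorm(length(counts), 0, noise$read_noise_sd) +
      noise$offset
    counts <- pmax(counts, 0)
    if (!is.null(d)) dim(counts) <- d
    counts
  })
}

# FFTs of ifftshifted PSF z-slices (convolution kernels), indexed by slice
psf_slice_otfs <- function(det_psf) {
  d <- dim(det_psf)
  lapply(seq_len(d[3]), function(j)
    fft2(ifftshift_nd(det_psf[, , j, drop = TRUE])))
}

#' Render one speckle-illuminated camera frame
#'
#' Noise-free signal: the phantom density is multiplied by the illumination
#' intensity plane-by-plane, convolved in 3-D with the detection PSF
#' (laterally periodic, FFT-based), and the focal plane of the result is
#' read out. Out-of-focus planes therefore contribute defocused light. The
#' signal is linear in the phantom density. If `noise` is supplied the
#' EMCCD model is applied.
#'
#' @param phantom a [make_beads()]-style `phantom`.
#' @param speckle `(ny, nx, nz)` illumination intensity (or `NULL` for
#'   uniform illumination).
#' @param det_psf detection PSF whose axial spacing matches the phantom's;
#'   centre slice = in-focus.
#' @param focal_index z index (into the phantom grid) of the focal plane.
#' @param noise optional [noise_model()].
#' @param seed seed for the noise draw.
#' @param photon_scale multiplicative conversion of density units to
#'   expected photons.
#' @param psf_otfs optional precomputed [psf_slice_otfs()] for speed.
#' @return a `(ny, nx)` matrix: expected photons, or counts when `noise`
#'   is given.
#' @export
render_frame <- function(phantom, speckle, det_psf, focal_index,
                         noise = NULL, seed = NULL, photon_scale = 1,
                         psf_otfs = NULL) {
  dens <- phantom$density
  d <- dim(dens)
  if (focal_index < 1 || focal_index > d[3]) stop("focal_index out of range")
  npz <- if (is.null(psf_otfs)) dim(det_psf)[3] else length(psf_otfs)
  cz <- centre_index(npz)
  if (is.null(psf_otfs)) psf_otfs <- psf_slice_otfs(det_psf)
  acc <- matrix(0 + 0i, d[1], d[2])
  for (z in seq_len(d[3])) {
    j <- cz + (focal_index - z)          # PSF slice at this defocus
    if (j < 1 || j > npz) next
    plane <- dens[, , z]
    if (!is.null(speckle)) plane <- plane * speckle[, , z]
    if (all(plane == 0)) next
    acc <- acc + fft2(plane) * psf_otfs[[j]]
  }
  out <- pmax(Re(ifft2(acc)), 0) * photon_scale
  if (!is.null(noise)) out <- apply_noise(out, noise, seed)
  out
}

#' Acquisition plan
#'
#' @param frames_per_layer speckle frames recorded per z layer (>= 2);
#'   50 for fixed samples, 100 for live imaging.
#' @param z_step nanostage step between layers (nm).
#' @param n_layers number of z layers.
#' @param frame_interval seconds per frame (50 fps camera: 0.02 s).
#' @param drift_per_frame `(dy, dx)` lateral drift per frame (nm).
#' @return object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(frames_per_layer = 50, z_step = 25,
                             n_layers = 24, frame_interval = 0.02,
                             drift_per_frame = c(0, 0)) {
  if (frames_per_layer < 2) stop("frames_per_layer must be >= 2")
  if (z_step <= 0) stop("z_step must be > 0")
  structure(list(frames_per_layer = as.integer(frames_per_layer),
                 z_step = z_step, n_layers = as.integer(n_layers),
                 frame_interval = frame_interval,
                 drift_per_frame = drift_per_frame),
            class = "acquisition_plan")
}

#' Acquire a raw 4-D speckle-illuminated stack
#'
#' For each z layer, renders `frames_per_layer` frames under independent
#' speckle realizations (rotating-diffuser model: fully decorrelated between
#' frames), applies optional linear lateral drift (cumulative over the
#' global frame counter) and EMCCD noise. Layers scan the phantom's z range
#' centred on its middle plane, at the phantom's axial spacing (the plan's
#' `z_step` must equal it). Expected photons are calibrated so that the
#' brightest in-focus voxel under mean illumination yields
#' `noise$photons_at_peak` photons.
#'
#' @param phantom a `phantom`.
#' @param plan an [acquisition_plan()].
#' @param optics an [optical_config()] whose grid matches the phantom.
#' @param mirror a [mirror_config()].
#' @param noise a [noise_model()] or `NULL` for noise-free output.
#' @param seed master seed; all per-frame pupil and noise seeds derive
#'   from it.
#' @return a list with `stack`, a `(ny, nx, t, z)` counts array of class
#'   `raw_stack` (dimension order documented in `attr(, "axis_order")`),
#'   `truth` (the phantom), `focal_indices`, and `photon_scale`.
#' @export
acquire_stack <- function(phantom, plan, optics, mirror = mirror_config(),
                          noise = noise_model(), seed = 1) {
  d <- dim(phantom$density)
  if (abs(plan$z_step - phantom$axial_spacing) > 1e-9)
    stop("plan z_step must equal the phantom axial spacing")
  if (plan$n_layers > d[3]) stop("more layers than phantom z planes")
  if (!all(optics$grid_shape == c(d[3], d[1], d[2])))
    stop("optics grid_shape must match the phantom grid")

  z0 <- centre_index(d[3]) - floor(plan$n_layers / 2)
  focal_indices <- seq.int(z0, length.out = plan$n_layers)
  z_nm <- (seq_len(d[3]) - 1) * phantom$axial_spacing
  support <- which(apply(phantom$density, 3, max) > 0)

  det_psf <- detection_psf(optics, shape = c(2L * d[3] - 1L, d[1], d[2]))
  psf_otfs <- psf_slice_otfs(det_psf)

  # photon calibration: brightest in-focus voxel under unit (mean) illumination
  ref <- 0
  if (length(support)) {
    for (fi in unique(pmin(pmax(focal_indices, min(support)), max(support)))) {
      fr <- render_frame(phantom, NULL, det_psf, fi, psf_otfs = psf_otfs)
      ref <- max(ref, max(fr))
    }
  }
  photon_scale <- if (!is.null(noise) && ref > 0)
    noise$photons_at_peak / ref else 1

  ny <- d[1]; nx <- d[2]; TT <- plan$frames_per_layer
  stack <- array(0, c(ny, nx, TT, plan$n_layers))
  gframe <- 0L
  for (li in seq_len(plan$n_layers)) {
    for (ti in seq_len(TT)) {
      gframe <- gframe + 1L
      spk <- NULL
      if (length(support)) {
        pupil <- sample_pupil(optics, derive_seed(seed, li, ti, 1L))
        sp <- speckle_planes(pupil, optics, mirror, z_nm[support])
        sp <- sp / mean(sp)
        spk <- array(1, c(ny, nx, d[3]))
        spk[, , support] <- sp
      }
      fr <- render_frame(phantom, spk, det_psf, focal_indices[li],
                         photon_scale = photon_scale, psf_otfs = psf_otfs)
      dr <- plan$drift_per_frame * (gframe - 1)
      if (any(dr != 0))
        fr <- pmax(fourier_shift2(fr, dr[1] / optics$lateral_spacing,
                                  dr[2] / optics$lateral_spacing), 0)
      if (!is.null(noise))
        fr <- apply_noise(fr, noise, derive_seed(seed, li, ti, 2L))
      stack[, , ti, li] <- fr
    }
  }
  attr(stack, "lateral_spacing") <- optics$lateral_spacing
  attr(stack, "axial_spacing") <- plan$z_step
  attr(stack, "axis_order") <- "(y, x, t, z); t fastest within a z-layer"
  attr(stack, "focal_z_nm") <- z_nm[focal_indices]
  attr(stack, "master_seed") <- as.integer(seed)
  class(stack) <- c("raw_stack", class(stack))
  list(stack = stack, truth = phantom, focal_indices = focal_indices,
       photon_scale = photon_scale)
}
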
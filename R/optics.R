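#' Optical system configuration
#'
#' Bundles the excitation/emission wavelengths, objective numerical aperture,
#' refractive indices and the simulation voxel grid. Lengths are in
#' nanometres. The lateral voxel spacing must satisfy the speckle Nyquist
#' bound `lateral_spacing <= wavelength_exc / (2 * numerical_aperture)`.
#'
#' @param wavelength_exc excitation wavelength (nm).
#' @param wavelength_em emission wavelength (nm).
#' @param numerical_aperture objective (detection) NA; must be positive and
#'   not exceed `n_immersion`.
#' @param illumination_na effective NA of the speckle illumination, i.e. the
#'   extent to which the diffused beam fills the objective back focal plane.
#'   This sets the axial correlation length of the random speckle; the
#'   default 0.7 reproduces the axial extent of the mirror-free effective
#'   speckle PSF observed on the reference system (~0.7 um). Must not exceed
#'   `numerical_aperture`.
#' @param n_immersion immersion-medium refractive index.
#' @param n_sample sample-medium refractive index (speckle propagates here).
#' @param lateral_spacing lateral voxel size (nm).
#' @param axial_spacing axial voxel size (nm).
#' @param grid_shape integer vector `(nz, ny, nx)` of voxel counts.
#' @return an object of class `optical_config`.
#' @examples
#' opt <- optical_config(grid_shape = c(16, 32, 32))
#' @export
optical_config <- function(wavelength_exc = 488, wavelength_em = 520,
                           numerical_aperture = 1.49, illumination_na = 0.7,
                           n_immersion = 1.518, n_sample = 1.33,
                           lateral_spacing = 40, axial_spacing = 20,
                           grid_shape = c(96L, 128L, 128L)) {
  stop_if_not_scalar_pos(wavelength_exc, "wavelength_exc")
  stop_if_not_scalar_pos(wavelength_em, "wavelength_em")
  stop_if_not_scalar_pos(numerical_aperture, "numerical_aperture")
  stop_if_not_scalar_pos(illumination_na, "illumination_na")
  if (illumination_na > numerical_aperture)
    stop("illumination_na must not exceed numerical_aperture")
  stop_if_not_scalar_pos(lateral_spacing, "lateral_spacing")
  stop_if_not_scalar_pos(axial_spacing, "axial_spacing")
  if (numerical_aperture > n_immersion)
    stop("numerical_aperture must not exceed n_immersion")
  if (lateral_spacing > wavelength_exc / (2 * numerical_aperture))
    stop("lateral_spacing violates the speckle Nyquist bound ",
         "wavelength_exc / (2 * NA)")
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stop("grid_shape must be (nz, ny, nx) positive voxel counts")
  structure(list(
    wavelength_exc = wavelength_exc, wavelength_em = wavelength_em,
    numerical_aperture = numerical_aperture,
    illumination_na = illumination_na, n_immersion = n_immersion,
    n_sample = n_sample, lateral_spacing = lateral_spacing,
    axial_spacing = axial_spacing, grid_shape = as.integer(grid_shape)),
    class = "optical_config")
}

#' Back-reflecting mirror configuration
#'
#' The mirror sits parallel to the focal plane at `gap_distance` nm above
#' z = 0 and reflects the illumination back through the sample, creating
#' axial standing-wave interference. Tilt is modelled as a transverse
#' frequency shift of the reflected angular spectrum (small-angle
#' approximation, valid to ~15 degrees).
#'
#' @param enabled logical; mirror present.
#' @param gap_distance mirror height above z = 0 (nm); default 100 um.
#' @param reflectance scalar amplitude reflectance in `[0, 1]`.
#' @param tilt_deg mirror tilt (degrees), `|tilt| <= 15`.
#' @return an object of class `mirror_config`.
#' @export
mirror_config <- function(enabled = TRUE, gap_distance = 1e5,
                          reflectance = 0.97, tilt_deg = 0) {
  if (gap_distance < 0) stop("gap_distance must be >= 0")
  if (reflectance < 0 || reflectance > 1)
    stop("reflectance must be in [0, 1]")
  if (abs(tilt_deg) > 15) stop("|tilt_deg| must be <= 15")
  structure(list(enabled = isTRUE(enabled), gap_distance = gap_distance,
                 reflectance = reflectance, tilt_deg = tilt_deg),
            class = "mirror_config")
}

#' Sample a random diffuser pupil field
#'
#' Draws circular-Gaussian complex amplitudes on the NA-limited disk of the
#' objective back focal plane (fully developed speckle statistics); zero
#' outside the disk. Identical seeds give identical pupils.
#'
#' @param optics an [optical_config()].
#' @param seed integer RNG seed.
#' @param na optional pupil radius in NA units; defaults to
#'   `optics$illumination_na`.
#' @return an object of class `pupil_field` holding the complex amplitude
#'   matrix (ky rows, kx columns, FFT frequency ordering), the NA-disk mask
#'   and the angular wavenumber grids.
#' @export
sample_pupil <- function(optics, seed, na = optics$illumination_na) {
  ny <- optics$grid_shape[2]; nx <- optics$grid_shape[3]
  k0 <- 2 * pi / optics$wavelength_exc
  kx <- 2 * pi * fft_freq(nx, optics$lateral_spacing)
  ky <- 2 * pi * fft_freq(ny, optics$lateral_spacing)
  kperp2 <- outer(ky^2, kx^2, `+`)
  mask <- if (na > 0) kperp2 <= (na * k0)^2 else
    matrix(FALSE, ny, nx)
  if (!any(mask))
    stop("NA disk contains no frequency samples on this grid; ",
         "enlarge the grid or the numerical aperture")
  amp <- with_seed(seed, {
    n <- ny * nx
    matrix(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
           ny, nx) / sqrt(2)
  })
  amp[!mask] <- 0i
  structure(list(amplitude = amp, mask = mask, kx = kx, ky = ky,
                 seed = as.integer(seed)), class = "pupil_field")
}

# Propagate a pupil to a set of z planes (nm), optionally adding the
# mirror-reflected counter-propagating branch. Returns |E|^2 as an
# (ny, nx, nplanes) array. Evanescent components (k_perp > n_sample * k0)
# are dropped; their count is attached as attribute "n_evanescent".
speckle_planes <- function(pupil, optics, mirror, z_values) {
  ny <- nrow(pupil$amplitude); nx <- ncol(pupil$amplitude)
  k0 <- 2 * pi / optics$wavelength_exc
  kn <- optics$n_sample * k0
  kperp2 <- outer(pupil$ky^2, pupil$kx^2, `+`)
  prop <- kperp2 <= kn^2
  kz <- matrix(0, ny, nx)
  kz[prop] <- sqrt(kn^2 - kperp2[prop])

  A <- pupil$amplitude
  n_evan <- sum(A != 0 & !prop)
  A[!prop] <- 0i

  use_mirror <- mirror$enabled && mirror$reflectance > 0
  if (use_mirror) {
    Ar <- pupil$amplitude
    if (mirror$tilt_deg != 0) {
      # transverse momentum kick 2 n k0 sin(tilt), quantized to the kx grid
      dkx <- 2 * pi / (nx * optics$lateral_spacing)
      s <- round(2 * kn * sin(mirror$tilt_deg * pi / 180) / dkx)
      Ar <- circshift_dim(Ar, s, 2L)
    }
    n_evan <- n_evan + sum(Ar != 0 & !prop)
    Ar[!prop] <- 0i
    Ar <- mirror$reflectance * Ar
    d <- mirror$gap_distance
  }

  out <- array(0, c(ny, nx, length(z_values)))
  for (j in seq_along(z_values)) {
    z <- z_values[j]
    spec <- A * exp(1i * kz * z)
    if (use_mirror) spec <- spec + Ar * exp(1i * kz * (2 * d - z))
    f <- ifft2(spec)
    out[, , j] <- Re(f)^2 + Im(f)^2
  }
  attr(out, "n_evanescent") <- n_evan
  out
}

#' Synthesize a speckle illumination volume
#'
#' Angular-spectrum propagation of one diffuser realization through the
#' sample medium. With the mirror enabled, each plane receives the coherent
#' sum of the direct and the mirror-reflected (counter-propagating) branch,
#' producing axial standing-wave interference with period
#' `wavelength_exc / (2 * n_sample)`. Intensities are normalized to unit
#' volume mean. With `reflectance = 0` or the mirror disabled, the output is
#' bitwise identical to the direct branch alone.
#'
#' @param pupil a [sample_pupil()] field on the same grid.
#' @param optics an [optical_config()].
#' @param mirror a [mirror_config()].
#' @param normalize logical; divide by the volume mean (default TRUE).
#' @return a non-negative `(ny, nx, nz)` intensity array of class
#'   `speckle_volume` with spacing attributes and the dropped evanescent
#'   component count in `attr(, "n_evanescent")`.
#' @export
synthesize_speckle <- function(pupil, optics, mirror = mirror_config(enabled = FALSE),
                               normalize = TRUE) {
  if (!identical(dim(pupil$amplitude),
                 c(optics$grid_shape[2], optics$grid_shape[3])) &&
      !all(dim(pupil$amplitude) == optics$grid_shape[2:3]))
    stop("pupil grid does not match optics grid")
  nz <- optics$grid_shape[1]
  z <- (seq_len(nz) - 1) * optics$axial_spacing
  I <- speckle_planes(pupil, optics, mirror, z)
  if (normalize) {
    m <- mean(I)
    if (m > 0) {
      nev <- attr(I, "n_evanescent")
      I <- I / m
      attr(I, "n_evanescent") <- nev
    }
  }
  attr(I, "lateral_spacing") <- optics$lateral_spacing
  attr(I, "axial_spacing") <- optics$axial_spacing
  class(I) <- c("speckle_volume", class(I))
  I
}
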
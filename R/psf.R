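#' Born-Wolf detection point spread function
#'
#' Evaluates the scalar Born-Wolf diffraction integral
#' \deqn{h(r, z) = \left| \int_0^1 J_0(k\,\mathrm{NA}\,\rho\,r)\,
#'   e^{-\,i k z \rho^2 \mathrm{NA}^2 / (2 n)}\, \rho\, d\rho \right|^2}
#' with \eqn{k = 2\pi/\lambda_{em}} and \eqn{n} the immersion index, on the
#' requested voxel grid, and normalizes the result to unit sum. The PSF is
#' even-symmetric laterally and axially with its global maximum at the
#' centre voxel.
#'
#' @param optics an [optical_config()]; uses `wavelength_em`,
#'   `numerical_aperture`, `n_immersion` and the voxel spacings.
#' @param shape `(nz, ny, nx)` voxel counts; defaults to the optics grid.
#' @param n_rho number of radial quadrature nodes.
#' @return a unit-sum `(ny, nx, nz)` array of class `psf_volume` with
#'   spacing attributes and `attr(, "normalization") = "unit-sum"`.
#' @export
detection_psf <- function(optics, shape = optics$grid_shape, n_rho = 120) {
  if (length(shape) != 3 || any(shape < 3))
    stop("shape must be (nz, ny, nx) with every dimension >= 3")
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  k <- 2 * pi / optics$wavelength_em
  na <- optics$numerical_aperture
  n <- optics$n_immersion

  x <- axis_coords(nx, optics$lateral_spacing)
  y <- axis_coords(ny, optics$lateral_spacing)
  z <- axis_coords(nz, optics$axial_spacing)
  r <- sqrt(outer(y^2, x^2, `+`))
  ru <- sort(unique(round(as.vector(r), 6)))
  ri <- match(round(r, 6), ru)

  # midpoint quadrature over rho; the J0 matrix is z-independent
  rho <- (seq_len(n_rho) - 0.5) / n_rho
  w <- rho / n_rho
  J <- besselJ(outer(ru, rho) * (k * na), 0)   # |ru| x n_rho
  Jw <- sweep(J, 2, w, `*`)

  psf <- array(0, c(ny, nx, nz))
  for (j in seq_len(nz)) {
    amp_re <- Jw %*% cos(-0.5 * k * z[j] * rho^2 * na^2 / n)
    amp_im <- Jw %*% sin(-0.5 * k * z[j] * rho^2 * na^2 / n)
    h <- amp_re^2 + amp_im^2
    psf[, , j] <- matrix(h[ri], ny, nx)
  }
  psf <- psf / sum(psf)
  attr(psf, "lateral_spacing") <- optics$lateral_spacing
  attr(psf, "axial_spacing") <- optics$axial_spacing
  attr(psf, "normalization") <- "unit-sum"
  class(psf) <- c("psf_volume", class(psf))
  psf
}

#' Periodic 3-D autocorrelation
#'
#' Computes the circular (periodic-boundary) autocorrelation of a volume via
#' the Wiener-Khinchin theorem and centres the zero lag at the middle voxel
#' `floor(dim/2) + 1`. The result is inversion-symmetric and its global
#' maximum, at zero lag, equals `sum(v^2)`.
#'
#' @param volume a finite numeric 3-D array.
#' @return centred autocorrelation array of the same shape.
#' @export
autocorrelation_3d <- function(volume) {
  if (length(dim(volume)) != 3) stop("volume must be a 3-D array")
  if (!all(is.finite(volume))) stop("volume must be finite")
  F <- fftn(volume)
  ac <- Re(ifftn(Re(F)^2 + Im(F)^2))
  fftshift_nd(ac)
}

#' Effective speckle PSF
#'
#' The resolution-bearing kernel of speckle fluctuation imaging: the
#' autocorrelation of the product of the speckle illumination intensity and
#' the detection PSF, peak-normalized with zero lag at the centre voxel.
#'
#' @param speckle a `(ny, nx, nz)` speckle intensity volume.
#' @param det_psf a detection PSF on the same grid.
#' @return peak-normalized `psf_volume` array.
#' @export
effective_speckle_psf <- function(speckle, det_psf) {
  if (!all(dim(speckle) == dim(det_psf)))
    stop("speckle and detection PSF grids do not match")
  ac <- autocorrelation_3d(unclass(speckle) * unclass(det_psf))
  ac <- ac / max(ac)
  attr(ac, "lateral_spacing") <- attr(speckle, "lateral_spacing")
  attr(ac, "axial_spacing") <- attr(speckle, "axial_spacing")
  attr(ac, "normalization") <- "unit-peak"
  class(ac) <- c("psf_volume", class(ac))
  ac
}

#' Full width at half maximum of a sampled profile
#'
#' Locates the peak, establishes a local baseline, and measures the width of
#' the central lobe at half of the peak height above that baseline, with
#' half-level crossings found by linear interpolation between samples.
#'
#' The baseline is, on each side of the peak, the first genuine local
#' minimum encountered walking outward (a minimum counts once the profile
#' rebounds by more than `rebound_frac` of the peak-to-minimum range); if
#' the profile decays monotonically the endpoint value is used. This handles
#' oscillatory profiles (e.g. axial interference sidelobes), where the
#' relevant baseline is the first fringe valley rather than the far tail.
#' Alternatively `baseline_window` (nm) restricts the baseline search to
#' `peak +/- baseline_window`.
#'
#' @param profile numeric vector with a global maximum away from both ends.
#' @param spacing sample spacing (nm).
#' @param baseline_window optional half-window (nm) for the baseline search.
#' @param rebound_frac rebound fraction defining a genuine valley.
#' @return the FWHM in nm.
#' @export
fwhm <- function(profile, spacing, baseline_window = NULL,
                 rebound_frac = 0.05) {
  n <- length(profile)
  if (n < 3) stop("profile too short")
  m <- which.max(profile)
  if (m == 1L || m == n)
    stop("profile peak must not be at an endpoint")
  peak <- profile[m]

  side_baseline <- function(idx) {
    # idx: sample indices walking outward from the peak
    p <- profile[idx]
    tol <- rebound_frac * (peak - min(profile))
    run_min <- p[1]
    for (i in seq_along(p)) {
      if (p[i] < run_min) run_min <- p[i]
      if (p[i] > run_min + tol) return(run_min)
    }
    run_min
  }

  if (!is.null(baseline_window)) {
    hw <- max(1L, round(baseline_window / spacing))
    lo <- max(1L, m - hw); hi <- min(n, m + hw)
    baseline <- min(profile[lo:hi])
  } else {
    baseline <- min(side_baseline(seq.int(m - 1L, 1L)),
                    side_baseline(seq.int(m + 1L, n)))
  }

  half <- baseline + 0.5 * (peak - baseline)

  cross_out <- function(idx, side) {
    # walk outward within the central lobe only: stop at the first genuine
    # rebound (fringe valley passed) without a crossing
    prev <- m
    tol <- rebound_frac * (peak - min(profile))
    run_min <- peak
    for (i in idx) {
      if (profile[i] <= half) {
        frac <- (profile[prev] - half) / (profile[prev] - profile[i])
        return(abs(prev - m) + frac)
      }
      if (profile[i] < run_min) run_min <- profile[i]
      if (profile[i] > run_min + tol) break
      prev <- i
    }
    stop(sprintf("half level never crossed on the %s side", side))
  }

  left <- cross_out(seq.int(m - 1L, 1L), "left")
  right <- cross_out(seq.int(m + 1L, n), "right")
  (left + right) * spacing
}
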
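#' Estimate the sub-pixel shift between two frames
#'
#' Phase correlation locates the integer-pixel displacement; a 20x
#' Fourier-domain upsampled cross-correlation around that peak refines it to
#' sub-pixel precision. Returns `(dy, dx)` such that
#' `moving(y, x) ~ reference(y - dy, x - dx)`.
#'
#' @param reference,moving same-shape, non-constant matrices.
#' @param upsample sub-pixel refinement factor.
#' @return numeric `(dy, dx)` in pixels.
#' @export
estimate_shift <- function(reference, moving, upsample = 20) {
  if (!all(dim(reference) == dim(moving))) stop("frames differ in shape")
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("cannot register a constant image")
  ny <- nrow(reference); nx <- ncol(reference)
  Fr <- fft2(reference - mean(reference))
  Fm <- fft2(moving - mean(moving))
  R <- Fr * Conj(Fm)
  Rn <- R / pmax(Mod(R), 1e-12)
  pc <- Re(ifft2(Rn))
  pk <- which(pc == max(pc), arr.ind = TRUE)[1, ]
  # wrap to signed lags; peak at -d for moving = shifted reference
  lag <- function(i, n) { i <- i - 1; if (i > n / 2) i - n else i }
  d0 <- c(lag(pk[1], ny), lag(pk[2], nx))
  d0 <- -d0

  # upsampled cross-correlation (not phase-normalized) around d0
  fy <- fft_freq(ny); fx <- fft_freq(nx)
  span <- seq(-1.5, 1.5, by = 1 / upsample)
  cy <- d0[1] + span; cx <- d0[2] + span
  # C(u, v) = sum_k R(k) exp(+2 pi i (fy u + fx v)) evaluated at -d candidates
  Ey <- exp(2i * pi * outer(fy, -cy))          # ny x |cy|
  Ex <- exp(2i * pi * outer(fx, -cx))
  C <- Re(t(Ey) %*% R %*% Ex)
  ij <- which(C == max(C), arr.ind = TRUE)[1, ]
  c(dy = cy[ij[1]], dx = cx[ij[2]])
}

#' Register a raw stack against per-layer mean references
#'
#' Each frame is aligned to the temporal mean of its z layer by Fourier-shift
#' resampling of the phase-correlation shift estimate. Because drift smears
#' the initial mean reference, the estimate is refined over `passes`
#' rounds, re-averaging the aligned frames between rounds. Frame count and
#' (up to interpolation leakage) intensity sums are preserved.
#'
#' @param raw a `(ny, nx, t, z)` `raw_stack` (or plain array).
#' @param passes refinement rounds (2 suffices for linear drift).
#' @param max_shift largest credible per-frame shift (px). Single speckle
#'   frames can be noise-dominated, where phase correlation returns an
#'   arbitrary peak; estimates beyond this gate are treated as failed and
#'   the frame is left in place (count in `attr(, "n_rejected")`).
#' @return list with `stack` (registered, same shape/attributes) and
#'   `drift`, a data frame `(t, z, dy_px, dx_px, method)` of total applied
#'   shifts.
#' @export
register_stack <- function(raw, passes = 2, max_shift = 10) {
  d <- dim(raw)
  if (length(d) != 4) stop("raw must be a (ny, nx, t, z) array")
  if (d[3] < 2) stop("need at least 2 frames per layer")
  out <- raw
  total <- array(0, c(d[3], d[4], 2))
  n_rej <- 0L
  for (pass in seq_len(passes)) {
    moved <- FALSE
    for (z in seq_len(d[4])) {
      ref <- apply(out[, , , z, drop = FALSE], c(1, 2), mean)
      for (t in seq_len(d[3])) {
        sh <- estimate_shift(ref, out[, , t, z])
        if (max(abs(sh)) > max_shift) {
          n_rej <- n_rej + 1L
          next
        }
        if (any(sh != 0)) {
          out[, , t, z] <- fourier_shift2(out[, , t, z], -sh[1], -sh[2])
          moved <- TRUE
        }
        total[t, z, ] <- total[t, z, ] + sh
      }
    }
    if (!moved) break
  }
  drift <- do.call(rbind, lapply(seq_len(d[4]), function(z)
    data.frame(t = seq_len(d[3]), z = z, dy_px = total[, z, 1],
               dx_px = total[, z, 2], method = "phase-correlation")))
  res <- list(stack = out, drift = drift)
  attr(res, "n_rejected") <- n_rej
  res
}

#' Write a drift table to CSV
#' @param drift data frame from [register_stack()].
#' @param path output file.
#' @export
write_drift_table <- function(drift, path) {
  utils::write.csv(drift, path, row.names = FALSE)
  invisible(path)
}

#' Correct axial distortion from refractive-index mismatch
#'
#' Nominal (stage) z positions overestimate true depth in a lower-index
#' sample medium: a feature recorded at stage position z sits at
#' `z * n_sample / n_immersion`. The volume is resampled along z by cubic
#' (Keys) interpolation onto the corrected coordinate, with amplitudes
#' scaled by the inverse factor so the integrated intensity is preserved.
#'
#' @param volume `(ny, nx, nz)` array, z spacing uniform.
#' @param n_immersion,n_sample refractive indices.
#' @return rescaled volume of the same shape (content compressed toward
#'   z index 1; vacated planes are zero).
#' @export
axial_rescale <- function(volume, n_immersion, n_sample) {
  if (n_immersion <= 0 || n_sample <= 0) stop("indices must be positive")
  s <- n_sample / n_immersion
  if (abs(s - 1) < 1e-12) return(volume)
  nz <- dim(volume)[3]
  # output plane i holds input evaluated at (i-1)/s (same dz grid)
  at <- (seq_len(nz) - 1) / s + 1
  W <- cubic_interp_matrix(nz, at)
  out <- apply_along_z(volume, W) / s
  keep_attrs(out, volume)
}

keep_attrs <- function(out, src) {
  for (a in c("lateral_spacing", "axial_spacing"))
    attr(out, a) <- attr(src, a)
  out
}

#' Align two channels along z
#'
#' Corrects a measured chromatic axial offset (typically below 1 um between
#' the 488 and 633 nm channels) by resampling channel b along z by
#' `-z_offset` with cubic interpolation.
#'
#' @param stack_a,stack_b `(ny, nx, nz)` volumes on the same z grid.
#' @param z_offset axial offset of channel b relative to a (nm);
#'   `|z_offset| <= 2000`.
#' @param axial_spacing z spacing (nm).
#' @return list `(a, b)` with channel b aligned to a.
#' @export
align_channels <- function(stack_a, stack_b, z_offset, axial_spacing) {
  if (abs(z_offset) > 2000)
    stop("z_offset beyond the supported +/- 2 um correction range")
  nz <- dim(stack_b)[3]
  if (abs(z_offset) >= nz * axial_spacing)
    stop("z_offset exceeds the stack extent")
  if (z_offset == 0) return(list(a = stack_a, b = stack_b))
  sh <- z_offset / axial_spacing
  W <- cubic_interp_matrix(nz, seq_len(nz) + sh)
  list(a = stack_a, b = keep_attrs(apply_along_z(stack_b, W), stack_b))
}
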
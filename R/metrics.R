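#' Structural similarity index (SSIM)
#'
#' Mean SSIM over the image with the standard 11x11 Gaussian window
#' (sigma 1.5) and constants K1 = 0.01, K2 = 0.03; the dynamic range is the
#' joint value range of the two images. Symmetric in its arguments.
#'
#' @param image_a,image_b same-shape matrices.
#' @param sigma Gaussian window standard deviation (pixels).
#' @param half_width window half width (pixels).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(image_a, image_b, sigma = 1.5, half_width = 5) {
  if (!all(dim(image_a) == dim(image_b))) stop("shape mismatch")
  if (any(dim(image_a) < 2 * half_width + 1)) stop("window does not fit")
  L <- max(image_a, image_b) - min(image_a, image_b)
  if (L == 0) return(1)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  g <- exp(-((-half_width):half_width)^2 / (2 * sigma^2))
  g <- g / sum(g)
  K <- outer(g, g)
  ny <- nrow(image_a); nx <- ncol(image_a)
  Kf <- fft2(ifftshift_nd(embed_centred3(K, c(ny, nx))))
  smooth <- function(x) Re(ifft2(fft2(x) * Kf))
  mu_a <- smooth(image_a); mu_b <- smooth(image_b)
  va <- smooth(image_a^2) - mu_a^2
  vb <- smooth(image_b^2) - mu_b^2
  cab <- smooth(image_a * image_b) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Image decorrelation resolution analysis
#'
#' Reference-free resolution estimation: the normalized image spectrum is
#' correlated with the spectrum under a series of `n_radii` low-pass masks,
#' repeated for `n_widths` Gaussian high-pass filtered copies of the
#' spectrum; the highest local-maximum position across all decorrelation
#' curves is the cutoff frequency `k_c` (in Nyquist units) and the
#' resolution is `2 * pixel / k_c`. In `axial_sector` mode the spectrum is
#' first restricted to a sector of `sector_deg` full opening angle about the
#' axial (row) frequency axis, capturing z-direction content of an xz slice.
#'
#' @param image non-constant matrix (for axial mode: rows = z).
#' @param pixel pixel size (nm).
#' @param mode `"lateral"` or `"axial_sector"`.
#' @param n_radii number of mask radii.
#' @param n_widths number of high-pass widths (log-spaced).
#' @param sector_deg full sector opening angle (degrees).
#' @return resolution in nm with `attr(, "kc")` (Nyquist units); flagged
#'   `"indeterminate"` with value `NA` when no decorrelation peak exists.
#' @export
decorr_resolution <- function(image, pixel, mode = c("lateral", "axial_sector"),
                              n_radii = 50, n_widths = 10,
                              sector_deg = 22.5) {
  mode <- match.arg(mode)
  if (stats::sd(image) == 0) stop("image is constant")
  ny <- nrow(image); nx <- ncol(image)
  Fi <- fftshift_nd(fft2(image - mean(image)))
  ry <- (seq_len(ny) - centre_index(ny)) / (ny / 2)
  rx <- (seq_len(nx) - centre_index(nx)) / (nx / 2)
  rad <- sqrt(outer(ry^2, rx^2, `+`))
  if (mode == "axial_sector") {
    ang <- atan2(abs(outer(rep(1, ny), rx)), abs(outer(ry, rep(1, nx))))
    keep <- ang <= (sector_deg / 2) * pi / 180
    Fi[!keep] <- 0i
  }
  Fn <- Fi / pmax(Mod(Fi), .Machine$double.xmin)
  Fn[Mod(Fi) == 0] <- 0i

  inside <- rad <= 1
  ord <- order(rad[inside])
  rv <- rad[inside][ord]
  radii <- seq(1 / n_radii, 1, length.out = n_radii)
  idx_at <- findInterval(radii, rv)

  curve_for <- function(Fh) {
    # d(r) = Re<Fh, Fn 1_{rad<=r}> / (||Fh|| * ||Fn 1_{rad<=r}||)
    a <- Re(Fh * Conj(Fn))[inside][ord]
    b <- (Mod(Fn)^2)[inside][ord]
    ca <- cumsum(a); cb <- cumsum(b)
    nf <- sqrt(sum(Mod(Fh)^2))
    den <- nf * sqrt(cb[pmax(idx_at, 1)])
    val <- ca[pmax(idx_at, 1)] / pmax(den, .Machine$double.xmin)
    val[idx_at == 0] <- 0
    val
  }

  local_max_pos <- function(dcurve) {
    # position of the curve's interior maximum; curves that only rise into
    # the noise-dominated band edge (maximum at the last radius) carry no
    # decorrelation peak
    n <- length(dcurve)
    i <- which.max(dcurve)
    if (i == n || dcurve[i] < 0.05) return(NA_real_)
    radii[i]
  }

  widths <- exp(seq(log(0.15), log(1.5), length.out = n_widths))
  kc <- local_max_pos(curve_for(Fi))
  for (w in widths) {
    Hp <- 1 - exp(-rad^2 / (2 * w^2))
    p <- local_max_pos(curve_for(Fi * Hp))
    if (!is.na(p) && (is.na(kc) || p > kc)) kc <- p
  }
  if (is.na(kc)) {
    res <- NA_real_
    attr(res, "flag") <- "indeterminate"
    return(res)
  }
  res <- 2 * pixel / kc
  attr(res, "kc") <- kc
  res
}

#' Orthogonal FWHM of an isolated peak in a volume
#'
#' Extracts 1-D profiles along x, y and z through the peak voxel and passes
#' each to [fwhm()].
#'
#' @param volume `(ny, nx, nz)` array.
#' @param peak integer `(iy, ix, iz)` voxel of the peak; found from the
#'   global maximum when omitted.
#' @param lateral_spacing,axial_spacing voxel sizes (nm); taken from the
#'   volume's attributes when present.
#' @param baseline_window passed to [fwhm()].
#' @param smooth odd moving-average window (samples) applied to each profile
#'   before the width measurement; 1 = none. Use 3 for profiles carrying
#'   residual speckle/cumulant noise.
#' @param rebound_frac passed to [fwhm()].
#' @return named vector `(fwhm_y, fwhm_x, fwhm_z)` in nm.
#' @export
bead_fwhm_3d <- function(volume, peak = NULL,
                         lateral_spacing = attr(volume, "lateral_spacing"),
                         axial_spacing = attr(volume, "axial_spacing"),
                         baseline_window = NULL, smooth = 1,
                         rebound_frac = 0.05) {
  if (is.null(peak)) {
    peak <- which(volume == max(volume), arr.ind = TRUE)[1, ]
  }
  prep <- function(p) {
    if (smooth > 1) {
      k <- rep(1 / smooth, smooth)
      ps <- as.numeric(stats::filter(p, k, sides = 2))
      ps[is.na(ps)] <- p[is.na(ps)]
      ps
    } else p
  }
  c(fwhm_y = fwhm(prep(volume[, peak[2], peak[3]]), lateral_spacing,
                  baseline_window, rebound_frac),
    fwhm_x = fwhm(prep(volume[peak[1], , peak[3]]), lateral_spacing,
                  baseline_window, rebound_frac),
    fwhm_z = fwhm(prep(volume[peak[1], peak[2], ]), axial_spacing,
                  baseline_window, rebound_frac))
}

#' Resolution report with isotropy ratio
#'
#' @param lateral,axial resolutions (nm), positive.
#' @param method label, e.g. `"decorrelation"` or `"FWHM"`.
#' @return object of class `resolution_report` with fields `lateral`,
#'   `axial` and `rir = axial / lateral` (the resolution isotropy ratio;
#'   1 = isotropic). Values are rounded only for display.
#' @export
resolution_report <- function(lateral, axial, method = "decorrelation") {
  if (lateral <= 0 || axial <= 0) stop("resolutions must be positive")
  structure(list(lateral = lateral, axial = axial, rir = axial / lateral,
                 method = method),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("resolution (%s): lateral %.1f nm, axial %.1f nm, RIR %.2f\n",
              x$method, x$lateral, x$axial, x$rir))
  invisible(x)
}

# 4-connected component labelling (small masks)
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(i, j), 1)
      lab[i, j] <- cur
      while (nrow(queue) > 0) {
        p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= ny && q[2] >= 1 && q[2] <= nx &&
              mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue <- rbind(queue, q)
          }
        }
      }
    }
  }
  lab
}

#' Track particles across a frame series
#'
#' Per frame: intensity threshold, 4-connected component labelling and
#' intensity-weighted centroids. Tracks are built by greedy nearest-neighbour
#' linking gated at `max_link_distance`; unmatched detections start new
#' tracks. Per-track speed is the total path length divided by elapsed time.
#'
#' @param frames `(ny, nx, t)` image series (>= 2 frames).
#' @param pixel pixel size (nm).
#' @param frame_interval seconds between frames.
#' @param min_intensity detection threshold (absolute counts).
#' @param max_link_distance linking gate (nm per frame).
#' @return object of class `track_set`: data frame `positions`
#'   `(track, frame, t_s, y_nm, x_nm)` and data frame `speeds`
#'   `(track, n_points, path_nm, speed_nm_s)`.
#' @export
track_particles <- function(frames, pixel, frame_interval, min_intensity,
                            max_link_distance = 500) {
  d <- dim(frames)
  if (length(d) != 3 || d[3] < 2) stop("need a (ny, nx, t) series")
  detect <- function(img) {
    mask <- img >= min_intensity
    if (!any(mask)) return(matrix(numeric(0), 0, 2))
    lab <- label_components(mask)
    ids <- seq_len(max(lab))
    t(vapply(ids, function(k) {
      w <- which(lab == k, arr.ind = TRUE)
      iw <- img[lab == k]
      c(sum(w[, 1] * iw) / sum(iw), sum(w[, 2] * iw) / sum(iw)) * pixel
    }, numeric(2)))
  }
  dets <- lapply(seq_len(d[3]), function(t) detect(frames[, , t]))

  track_pos <- list(); track_last <- list(); track_frames <- list()
  for (t in seq_len(d[3])) {
    D <- dets[[t]]
    if (nrow(D) == 0) next
    open <- which(vapply(track_frames, function(fr) fr[length(fr)] == t - 1,
                         logical(1)))
    used <- rep(FALSE, nrow(D))
    if (length(open)) {
      # greedy: repeatedly link the globally closest (track, detection) pair
      repeat {
        best <- c(NA, NA); bd <- Inf
        for (k in open) {
          lp <- track_last[[k]]
          for (m in which(!used)) {
            dd <- sqrt(sum((D[m, ] - lp)^2))
            if (dd < bd) { bd <- dd; best <- c(k, m) }
          }
        }
        if (!is.finite(bd) || bd > max_link_distance) break
        k <- best[1]; m <- best[2]
        track_pos[[k]] <- rbind(track_pos[[k]], D[m, ])
        track_last[[k]] <- D[m, ]
        track_frames[[k]] <- c(track_frames[[k]], t)
        used[m] <- TRUE
        open <- setdiff(open, k)
        if (!length(open) || all(used)) break
      }
    }
    for (m in which(!used)) {
      track_pos[[length(track_pos) + 1]] <- D[m, , drop = FALSE]
      track_last[[length(track_last) + 1]] <- D[m, ]
      track_frames[[length(track_frames) + 1]] <- t
    }
  }

  pos_rows <- list(); spd_rows <- list()
  for (k in seq_along(track_pos)) {
    P <- track_pos[[k]]; fr <- track_frames[[k]]
    pos_rows[[k]] <- data.frame(track = k, frame = fr,
                                t_s = (fr - 1) * frame_interval,
                                y_nm = P[, 1], x_nm = P[, 2])
    path <- if (nrow(P) > 1) sum(sqrt(rowSums(diff(P)^2))) else 0
    el <- (fr[length(fr)] - fr[1]) * frame_interval
    spd_rows[[k]] <- data.frame(track = k, n_points = nrow(P),
                                path_nm = path,
                                speed_nm_s = if (el > 0) path / el else 0)
  }
  structure(list(positions = do.call(rbind, pos_rows),
                 speeds = do.call(rbind, spd_rows)),
            class = "track_set")
}
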
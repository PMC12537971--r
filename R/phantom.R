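# Synthetic fluorophore phantoms: density grids on the simulation voxel
# lattice, rasterized with 3x3x3 sub-voxel sampling and per-object mass
# normalized to the analytic object volume (in voxel units), so total mass
# is exact regardless of sub-voxel placement.

new_phantom <- function(density, lateral_spacing, axial_spacing,
                        positions = NULL) {
  structure(list(density = density, lateral_spacing = lateral_spacing,
                 axial_spacing = axial_spacing, positions = positions),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("phantom: %d x %d x %d voxels (%g nm lateral, %g nm axial), total mass %.4g\n",
              d[1], d[2], d[3], x$lateral_spacing, x$axial_spacing,
              sum(x$density)))
  invisible(x)
}

# uniform random positions (nm) with minimum pairwise spacing, by rejection
sample_positions <- function(n, extent_nm, margin_nm, min_spacing, seed,
                             max_tries = 5000L) {
  with_seed(seed, {
    pos <- matrix(NA_real_, n, 3)
    lo <- margin_nm; hi <- extent_nm - margin_nm
    if (any(hi <= lo)) stop("bounds too small for the requested margin")
    placed <- 0L; tries <- 0L
    while (placed < n) {
      cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]),
                stats::runif(1, lo[3], hi[3]))
      ok <- placed == 0L ||
        min(sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2))) >= min_spacing
      if (ok) { placed <- placed + 1L; pos[placed, ] <- cand }
      tries <- tries + 1L
      if (tries > max_tries)
        stop("bounds too small to place ", n,
             " objects at the requested minimum spacing")
    }
    pos
  })
}

# rasterize one spherical(-shell) object into `density` (modified in place
# via return); membership(r2) gives the sub-sample indicator
rasterize_radial <- function(density, centre_nm, r_outer, membership,
                             mass_vox, dxy, dz, ss = 3L) {
  d <- dim(density)
  off <- (seq_len(ss) - (ss + 1) / 2) / ss      # sub-voxel offsets
  ry <- r_outer / dxy + 1; rx <- r_outer / dxy + 1; rz <- r_outer / dz + 1
  cy <- centre_nm[1] / dxy + 1; cx <- centre_nm[2] / dxy + 1
  cz <- centre_nm[3] / dz + 1
  iy <- max(1, floor(cy - ry)):min(d[1], ceiling(cy + ry))
  ix <- max(1, floor(cx - rx)):min(d[2], ceiling(cx + rx))
  iz <- max(1, floor(cz - rz)):min(d[3], ceiling(cz + rz))
  sub <- expand.grid(oy = off, ox = off, oz = off)
  w <- array(0, c(length(iy), length(ix), length(iz)))
  yy <- (iy - 1) * dxy; xx <- (ix - 1) * dxy; zz <- (iz - 1) * dz
  for (s in seq_len(nrow(sub))) {
    dy2 <- (yy + sub$oy[s] * dxy - centre_nm[1])^2
    dx2 <- (xx + sub$ox[s] * dxy - centre_nm[2])^2
    dz2 <- (zz + sub$oz[s] * dz - centre_nm[3])^2
    r2 <- outer(outer(dy2, dx2, `+`), dz2, `+`)
    w <- w + membership(r2)
  }
  tot <- sum(w)
  if (tot > 0) {
    density[iy, ix, iz] <- density[iy, ix, iz] + w * (mass_vox / tot)
  }
  density
}

#' Fluorescent bead phantom
#'
#' Places `n` uniform-density spheres at uniformly random positions with a
#' minimum pairwise spacing. Each bead's integrated mass equals the analytic
#' sphere volume in voxel units times `brightness`, independent of sub-voxel
#' placement.
#'
#' @param n number of beads (0 gives an empty phantom).
#' @param diameter bead diameter (nm); default 100 nm.
#' @param grid_shape `(nz, ny, nx)` voxel counts.
#' @param lateral_spacing,axial_spacing voxel sizes (nm).
#' @param min_spacing minimum centre-to-centre distance (nm).
#' @param margin keep-out border (nm) from the volume faces.
#' @param brightness per-bead density scale.
#' @param seed integer seed (ignored when `positions` is given).
#' @param positions optional `n x 3` matrix of (y, x, z) centres in nm,
#'   overriding random placement.
#' @return a `phantom` object; `positions` (nm) stored alongside.
#' @export
make_beads <- function(n, diameter = 100, grid_shape = c(48L, 64L, 64L),
                       lateral_spacing = 80, axial_spacing = 25,
                       min_spacing = 4 * diameter, margin = NULL,
                       brightness = 1, seed = 1, positions = NULL) {
  d <- c(grid_shape[2], grid_shape[3], grid_shape[1])   # (ny, nx, nz)
  density <- array(0, d)
  if (n == 0)
    return(new_phantom(density, lateral_spacing, axial_spacing,
                       matrix(numeric(0), 0, 3)))
  extent <- c((d[1] - 1) * lateral_spacing, (d[2] - 1) * lateral_spacing,
              (d[3] - 1) * axial_spacing)
  margin <- margin %||% (diameter + c(2 * lateral_spacing, 2 * lateral_spacing,
                                      2 * axial_spacing))
  if (is.null(positions))
    positions <- sample_positions(n, extent, margin, min_spacing, seed)
  r <- diameter / 2
  mass_vox <- brightness * (4 / 3) * pi * r^3 /
    (lateral_spacing^2 * axial_spacing)
  for (i in seq_len(nrow(positions))) {
    density <- rasterize_radial(density, positions[i, ], r,
                                function(r2) r2 <= r^2, mass_vox,
                                lateral_spacing, axial_spacing)
  }
  new_phantom(density, lateral_spacing, axial_spacing, positions)
}

#' Hollow spherical-shell phantom
#'
#' Spherical shells (membrane-bound organelle stand-ins) with fluorophore
#' density confined to `[outer_diameter/2 - shell_thickness,
#' outer_diameter/2]` and an empty lumen. Per-shell mass is normalized to
#' the analytic shell volume.
#'
#' @inheritParams make_beads
#' @param outer_diameter outer shell diameter (nm).
#' @param shell_thickness radial thickness (nm); must be less than
#'   `outer_diameter / 2`.
#' @return a `phantom` object.
#' @export
make_hollow_shells <- function(n, outer_diameter = 600, shell_thickness = 80,
                               grid_shape = c(48L, 64L, 64L),
                               lateral_spacing = 80, axial_spacing = 25,
                               min_spacing = 2 * outer_diameter,
                               margin = NULL, brightness = 1, seed = 1,
                               positions = NULL) {
  if (shell_thickness >= outer_diameter / 2)
    stop("shell_thickness must be less than outer_diameter / 2")
  d <- c(grid_shape[2], grid_shape[3], grid_shape[1])
  density <- array(0, d)
  if (n == 0)
    return(new_phantom(density, lateral_spacing, axial_spacing,
                       matrix(numeric(0), 0, 3)))
  extent <- c((d[1] - 1) * lateral_spacing, (d[2] - 1) * lateral_spacing,
              (d[3] - 1) * axial_spacing)
  margin <- margin %||% (outer_diameter / 2 +
                           c(2 * lateral_spacing, 2 * lateral_spacing,
                             2 * axial_spacing))
  if (is.null(positions))
    positions <- sample_positions(n, extent, margin, min_spacing, seed)
  r_out <- outer_diameter / 2
  r_in <- r_out - shell_thickness
  mass_vox <- brightness * (4 / 3) * pi * (r_out^3 - r_in^3) /
    (lateral_spacing^2 * axial_spacing)
  for (i in seq_len(nrow(positions))) {
    density <- rasterize_radial(density, positions[i, ], r_out,
                                function(r2) r2 <= r_out^2 & r2 >= r_in^2,
                                mass_vox, lateral_spacing, axial_spacing,
                                ss = 4L)
  }
  new_phantom(density, lateral_spacing, axial_spacing, positions)
}

#' Filament phantom
#'
#' Smooth random-walk tubes (microtubule stand-ins) rasterized with a
#' Gaussian cross-section of FWHM `thickness` and constant linear density:
#' the accumulated mass per unit arc length is uniform along each tube.
#'
#' @inheritParams make_beads
#' @param thickness tube FWHM (nm).
#' @param curvature direction jitter (radians per step) of the random walk;
#'   0 gives straight tubes.
#' @param start,direction optional `n x 3` matrices (nm and unit vectors,
#'   (y, x, z) order) fixing each tube's start and initial heading.
#' @return a `phantom` object.
#' @export
make_filaments <- function(n, thickness = 120, curvature = 0.05,
                           grid_shape = c(32L, 64L, 64L),
                           lateral_spacing = 80, axial_spacing = 25,
                           brightness = 1, seed = 1, start = NULL,
                           direction = NULL) {
  d <- c(grid_shape[2], grid_shape[3], grid_shape[1])
  density <- array(0, d)
  if (n == 0) return(new_phantom(density, lateral_spacing, axial_spacing))
  extent <- c((d[1] - 1) * lateral_spacing, (d[2] - 1) * lateral_spacing,
              (d[3] - 1) * axial_spacing)
  sigma <- thickness / (2 * sqrt(2 * log(2)))
  # arc-length step ~ sigma/2, snapped so a voxel is an integer number of
  # steps: straight tubes then rasterize with exactly uniform cross-section
  ds <- lateral_spacing / max(1L, ceiling(2 * lateral_spacing / sigma))
  with_seed(seed, {
    for (i in seq_len(n)) {
      p <- if (!is.null(start)) start[i, ] else
        c(stats::runif(1, 0.2, 0.8) * extent[1],
          stats::runif(1, 0.2, 0.8) * extent[2],
          stats::runif(1, 0.3, 0.7) * extent[3])
      u <- if (!is.null(direction)) direction[i, ] else {
        v <- stats::rnorm(3); v[3] <- 0.2 * v[3]; v / sqrt(sum(v^2))
      }
      n_steps <- ceiling(1.5 * max(extent) / ds)
      pts <- matrix(NA_real_, n_steps, 3)
      for (s in seq_len(n_steps)) {
        pts[s, ] <- p
        p <- p + u * ds
        if (any(p < 0) || any(p > extent)) break
        if (curvature > 0) {
          u <- u + stats::rnorm(3, sd = curvature * sqrt(ds / lateral_spacing))
          u <- u / sqrt(sum(u^2))
        }
      }
      pts <- pts[stats::complete.cases(pts), , drop = FALSE]
      density <- splat_gaussian(density, pts, sigma, brightness * ds,
                                lateral_spacing, axial_spacing)
    }
    new_phantom(density, lateral_spacing, axial_spacing)
  })
}

# accumulate isotropic Gaussian kernels (in nm) at a set of points
splat_gaussian <- function(density, pts, sigma, amp, dxy, dz) {
  d <- dim(density)
  hw <- 3 * sigma
  for (s in seq_len(nrow(pts))) {
    c_nm <- pts[s, ]
    iy <- max(1, floor((c_nm[1] - hw) / dxy + 1)):min(d[1], ceiling((c_nm[1] + hw) / dxy + 1))
    ix <- max(1, floor((c_nm[2] - hw) / dxy + 1)):min(d[2], ceiling((c_nm[2] + hw) / dxy + 1))
    iz <- max(1, floor((c_nm[3] - hw) / dz + 1)):min(d[3], ceiling((c_nm[3] + hw) / dz + 1))
    gy <- exp(-((iy - 1) * dxy - c_nm[1])^2 / (2 * sigma^2))
    gx <- exp(-((ix - 1) * dxy - c_nm[2])^2 / (2 * sigma^2))
    gz <- exp(-((iz - 1) * dz - c_nm[3])^2 / (2 * sigma^2))
    density[iy, ix, iz] <- density[iy, ix, iz] +
      amp * outer(outer(gy, gx), gz)
  }
  density
}

#' Moving point-particle phantom
#'
#' Constant-speed particle tracks sampled at the frame interval, with
#' optional gradual direction change; particles reflect at the lateral
#' bounds (reflections are counted in `attr(, "n_reflections")`). Default
#' speeds are drawn uniformly in 60-100 nm/s, bracketing reported lysosome
#' velocities (~79-88 nm/s).
#'
#' @param n number of particles.
#' @param speed nm/s; a scalar applied to all particles, or `NULL` to draw
#'   per-particle speeds from `speed_range`.
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames.
#' @param grid_shape `(nz, ny, nx)`; particles move in the focal plane
#'   (constant z at the axial centre).
#' @param lateral_spacing,axial_spacing voxel sizes (nm).
#' @param speed_range range for randomly drawn speeds (nm/s).
#' @param turn_sd direction jitter (radians per frame).
#' @param seed integer seed.
#' @return object of class `moving_phantom`: positions array
#'   `(n, n_frames, 3)` in nm (y, x, z) plus rendering metadata.
#' @export
make_moving_particles <- function(n, speed = NULL, frame_interval = 1,
                                  n_frames = 30,
                                  grid_shape = c(9L, 64L, 64L),
                                  lateral_spacing = 80, axial_spacing = 100,
                                  speed_range = c(60, 100), turn_sd = 0,
                                  seed = 1) {
  if (!is.null(speed) && any(speed < 0)) stop("speed must be >= 0")
  ext <- c((grid_shape[2] - 1), (grid_shape[3] - 1)) * lateral_spacing
  z0 <- (centre_index(grid_shape[1]) - 1) * axial_spacing
  n_refl <- 0L
  pos <- with_seed(seed, {
    v <- if (is.null(speed)) stats::runif(n, speed_range[1], speed_range[2])
         else rep_len(speed, n)
    th <- stats::runif(n, 0, 2 * pi)
    p <- array(NA_real_, c(n, n_frames, 3))
    y <- stats::runif(n, 0.25, 0.75) * ext[1]
    x <- stats::runif(n, 0.25, 0.75) * ext[2]
    for (t in seq_len(n_frames)) {
      p[, t, 1] <- y; p[, t, 2] <- x; p[, t, 3] <- z0
      step <- v * frame_interval
      y <- y + step * sin(th); x <- x + step * cos(th)
      for (i in seq_len(n)) {        # reflect at lateral bounds
        if (y[i] < 0) { y[i] <- -y[i]; th[i] <- -th[i]; n_refl <<- n_refl + 1L }
        if (y[i] > ext[1]) { y[i] <- 2 * ext[1] - y[i]; th[i] <- -th[i]; n_refl <<- n_refl + 1L }
        if (x[i] < 0) { x[i] <- -x[i]; th[i] <- pi - th[i]; n_refl <<- n_refl + 1L }
        if (x[i] > ext[2]) { x[i] <- 2 * ext[2] - x[i]; th[i] <- pi - th[i]; n_refl <<- n_refl + 1L }
      }
      if (turn_sd > 0) th <- th + stats::rnorm(n, sd = turn_sd)
    }
    p
  })
  out <- structure(list(positions = pos, speeds = NULL,
                        frame_interval = frame_interval,
                        grid_shape = as.integer(grid_shape),
                        lateral_spacing = lateral_spacing,
                        axial_spacing = axial_spacing),
                   class = "moving_phantom")
  attr(out, "n_reflections") <- n_refl
  out
}

#' Rasterize one time point of a moving phantom
#'
#' @param mp a [make_moving_particles()] object.
#' @param frame frame index.
#' @param diameter rendered particle diameter (nm).
#' @param brightness per-particle density scale.
#' @return a static `phantom` for that frame.
#' @export
moving_phantom_frame <- function(mp, frame, diameter = 200, brightness = 1) {
  make_beads(n = dim(mp$positions)[1], diameter = diameter,
             grid_shape = mp$grid_shape,
             lateral_spacing = mp$lateral_spacing,
             axial_spacing = mp$axial_spacing, brightness = brightness,
             positions = matrix(mp$positions[, frame, ], ncol = 3))
}
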
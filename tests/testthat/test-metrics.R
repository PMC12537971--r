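# SSIM, decorrelation resolution, bead FWHM, isotropy report, tracking.

test_that("SSIM is 1 for identical images, symmetric, and shape-checked", {
  set.seed(1)
  a <- matrix(runif(64 * 64), 64)
  expect_equal(ssim(a, a), 1, tolerance = 1e-9)
  b <- a + matrix(rnorm(64 * 64, 0, 0.1), 64)
  expect_lt(abs(ssim(a, b) - ssim(b, a)), 1e-12)
  expect_lt(ssim(a, b), 1)
  expect_error(ssim(a, a[1:32, ]), "mismatch")
})

test_that("decorrelation analysis recovers constructed band limits", {
  img <- lowpass_noise(64, 0.5, 3) + 0.05 * matrix(rnorm(64 * 64), 64)
  r <- decorr_resolution(img, 1)
  expect_equal(as.numeric(r), 4, tolerance = 0.15)

  # invariance to intensity scale and offset
  r10 <- decorr_resolution(10 * img + 7, 1)
  expect_equal(as.numeric(r10), as.numeric(r), tolerance = 1e-6)

  # physical pixel size propagates linearly
  r_nm <- decorr_resolution(img, 80)
  expect_equal(as.numeric(r_nm), 80 * as.numeric(r), tolerance = 1e-6)

  expect_error(decorr_resolution(matrix(1, 32, 32), 1), "constant")
})

test_that("lowering the band limit never yields a finer decorrelation estimate", {
  res <- vapply(c(0.8, 0.6, 0.45, 0.3, 0.2), function(cut) {
    img <- lowpass_noise(64, cut, 17) + 0.05 * matrix(rnorm(64 * 64), 64)
    as.numeric(decorr_resolution(img, 1))
  }, numeric(1))
  expect_true(all(diff(res) >= 0))
})

test_that("the axial sector isolates anisotropic band limits", {
  # kz (rows) limited to 0.25 Nyquist, kx to 0.5
  set.seed(9)
  n <- 64
  img <- matrix(rnorm(n * n), n)
  F <- stats::fft(img)
  f <- c(seq.int(0, 31), seq.int(-32, -1)) / 32
  Fz <- outer(abs(f), rep(1, n)); Fx <- outer(rep(1, n), abs(f))
  F[Fz > 0.25 | Fx > 0.5] <- 0i
  img <- Re(stats::fft(F, inverse = TRUE)) / (n * n)
  img <- img + 0.05 * sd(img) * matrix(rnorm(n * n), n)

  ax <- as.numeric(decorr_resolution(img, 1, mode = "axial_sector"))
  lat <- as.numeric(decorr_resolution(img, 1))
  expect_equal(ax, 8, tolerance = 0.2)
  expect_equal(lat, 4, tolerance = 0.2)
})

test_that("bead FWHM recovers closed-form Gaussian widths in 3-D", {
  x <- (1:41) - 21
  g1 <- exp(-x^2 / (2 * (100 / 40)^2))          # sigma 100 nm at 40 nm voxels
  vol <- outer(outer(g1, g1), g1)
  f <- bead_fwhm_3d(vol, lateral_spacing = 40, axial_spacing = 40)
  expect_equal(unname(f), rep(2 * sqrt(2 * log(2)) * 100, 3),
               tolerance = 2 / 235)

  gz <- exp(-x^2 / (2 * (200 / 40)^2))          # sigma_z = 2 sigma_x
  vol2 <- outer(outer(g1, g1), gz)
  f2 <- bead_fwhm_3d(vol2, lateral_spacing = 40, axial_spacing = 40)
  expect_equal(unname(f2["fwhm_z"] / f2["fwhm_x"]), 2, tolerance = 0.02)
})

test_that("bead FWHM agrees with a dense Born-Wolf evaluation", {
  opt <- optical_config(grid_shape = c(49L, 33L, 33L), lateral_spacing = 40,
                        axial_spacing = 40)
  psf <- detection_psf(opt)
  f <- bead_fwhm_3d(unclass(psf), lateral_spacing = 40, axial_spacing = 40)
  # dense (4x finer) evaluation of the same integral as oracle
  fine <- optical_config(grid_shape = c(193L, 129L, 5L), lateral_spacing = 10,
                         axial_spacing = 10)
  dense <- detection_psf(fine, n_rho = 200)
  lat_o <- fwhm(dense[, axisim:::centre_index(5), axisim:::centre_index(193)], 10)
  axi_o <- fwhm(dense[axisim:::centre_index(129), axisim:::centre_index(5), ], 10)
  expect_equal(unname(f["fwhm_x"]), lat_o, tolerance = 0.05)
  expect_equal(unname(f["fwhm_z"]), axi_o, tolerance = 0.05)
})

test_that("resolution report computes the isotropy ratio", {
  rep1 <- resolution_report(108.5, 140.1)
  expect_equal(round(rep1$rir, 2), 1.29)
  expect_equal(resolution_report(100, 100)$rir, 1.0)
  expect_equal(round(resolution_report(140.1, 788)$rir, 2), 5.62)
  expect_error(resolution_report(-1, 5), "positive")
})

test_that("particle tracking recovers injected speeds", {
  render_tracks <- function(mp, n = 48, px = 80, amp = 5000, sd_noise = 2) {
    d <- dim(mp$positions)
    fr <- array(0, c(n, n, d[2]))
    for (t in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        cy <- mp$positions[i, t, 1] / px + 1
        cx <- mp$positions[i, t, 2] / px + 1
        fr[, , t] <- fr[, , t] +
          amp * outer(exp(-((1:n) - cy)^2 / 4), exp(-((1:n) - cx)^2 / 4))
      }
      fr[, , t] <- fr[, , t] + matrix(rnorm(n * n, 0, sd_noise), n)
    }
    fr
  }

  mp0 <- make_moving_particles(2, speed = 0, frame_interval = 1,
                               n_frames = 12, grid_shape = c(5L, 48L, 48L),
                               seed = 3)
  tr0 <- track_particles(render_tracks(mp0), pixel = 80, frame_interval = 1,
                         min_intensity = 200)
  expect_lt(max(tr0$speeds$speed_nm_s), 1)

  # seed chosen so the two tracks stay > 1 um apart (no blob merging)
  mp <- make_moving_particles(2, speed = 80, frame_interval = 1,
                              n_frames = 30, grid_shape = c(5L, 96L, 96L),
                              seed = 5)
  expect_equal(attr(mp, "n_reflections"), 0L)
  tr <- track_particles(render_tracks(mp, n = 96), pixel = 80,
                        frame_interval = 1, min_intensity = 200,
                        max_link_distance = 500)
  main <- tr$speeds[tr$speeds$n_points >= 25, ]
  expect_equal(nrow(main), 2)
  expect_equal(main$speed_nm_s, rep(80, 2), tolerance = 4 / 80)
})
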
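# Cumulant reconstruction chain: RL, DSI weighting, Fourier interpolation,
# cumulants, linearization, flattening, FRC and iteration selection.

test_that("Richardson-Lucy with a delta kernel is the identity and stays non-negative", {
  set.seed(1)
  im <- matrix(runif(32 * 32), 32)
  delta <- matrix(0, 32, 32); delta[17, 17] <- 1
  for (it in c(1, 7)) {
    out <- rl_deconvolve(im, delta, it)
    expect_lt(max(abs(out - im)), 1e-9)
  }
  expect_error(rl_deconvolve(im, delta, 0), "iterations")

  psf <- exp(-outer(((1:32) - 17)^2, ((1:32) - 17)^2, `+`) / (2 * 2^2))
  out <- rl_deconvolve(im, psf / sum(psf), 10)
  expect_true(all(out >= 0))
})

test_that("deconvolving a blurred point sharpens monotonically", {
  psf <- exp(-outer(((1:48) - 25)^2, ((1:48) - 25)^2, `+`) / (2 * 3^2))
  psf <- psf / sum(psf)
  blurred <- axisim:::fftshift_nd(
    Re(axisim:::ifft2(axisim:::fft2(axisim:::ifftshift_nd(psf)) *
                        axisim:::fft2(axisim:::ifftshift_nd(psf)))))
  ests <- rl_deconvolve(blurred, psf, 30, checkpoints = 1:30)
  w <- vapply(ests, function(e) fwhm(e[25, ], 1), numeric(1))
  expect_true(all(diff(w) <= 1e-9))
})

test_that("DSI weight is the temporal RMS", {
  fr <- array(2, c(4, 4, 5))
  expect_equal(dsi_weight(fr), matrix(2, 4, 4))
  fr2 <- array(0, c(1, 1, 3)); fr2[1, 1, ] <- c(0, 0, 3)
  expect_equal(dsi_weight(fr2)[1, 1], sqrt(3), tolerance = 1e-12)
  expect_error(dsi_weight(array(1, c(4, 4, 1))), "t >= 2")
})

test_that("reweighting then square root is scale-consistent", {
  fr <- array(2, c(3, 3, 4))
  W <- matrix(2, 3, 3)
  out <- reweight_linearize(fr, W)
  expect_equal(out, array(2, c(3, 3, 4)))
  expect_equal(reweight_linearize(array(0, c(3, 3, 4)), W),
               array(0, c(3, 3, 4)))
  set.seed(2)
  fr3 <- array(runif(36), c(3, 3, 4)); W3 <- matrix(runif(9), 3, 3)
  expect_lt(max(abs(reweight_linearize(fr3, W3)^2 -
                      as.vector(fr3) * rep(as.vector(W3), 4))), 1e-12)
})

test_that("Fourier interpolation reproduces band-limited content exactly", {
  n <- 32
  s <- outer(sin(2 * pi * 5 * (0:(n - 1)) / n),
             rep(1, n)) + outer(rep(1, n), cos(2 * pi * 3 * (0:(n - 1)) / n))
  up <- fourier_interpolate(s, 2L)
  truth <- outer(sin(2 * pi * 5 * ((0:63) / 2) / n), rep(1, 64)) +
    outer(rep(1, 64), cos(2 * pi * 3 * ((0:63) / 2) / n))
  expect_lt(max(abs(up - truth)), 1e-6)
  expect_equal(mean(up), mean(s), tolerance = 1e-9)
  cst <- fourier_interpolate(matrix(3.7, 16, 16), 2L)
  expect_equal(range(cst), c(3.7, 3.7), tolerance = 1e-12)
})

test_that("temporal cumulants equal brute-force lagged central moments", {
  expect_equal(temporal_cumulant(c(0, 0, 3), 2, 0), 2.0)
  expect_equal(temporal_cumulant(c(0, 0, 3), 3, 0), 2.0)
  expect_equal(temporal_cumulant(c(1, 3), 2, 0), 1.0)
  expect_equal(temporal_cumulant(c(1, 3), 3, 0), 0.0)
  expect_equal(temporal_cumulant(rep(4.2, 10), 2, 0), 0)
  expect_equal(temporal_cumulant(rep(4.2, 10), 3, 0), 0)

  set.seed(7)
  for (len in c(5, 17, 50)) for (ord in 2:3) for (lag in 0:2) {
    if (len - (ord - 1) * lag < 2) next
    x <- rnorm(len)
    expect_equal(temporal_cumulant(x, ord, lag),
                 cumulant_bruteforce(x, ord, lag), tolerance = 1e-10)
  }
  expect_error(temporal_cumulant(c(1, 2, 3), 3, 2), "lag span")
})

test_that("brightness linearization has the closed-form constant fixed point", {
  opt <- optical_config(lateral_spacing = 80, axial_spacing = 25,
                        grid_shape = c(9L, 16L, 16L))
  psf <- detection_psf(opt)
  v <- array(8, c(16, 16, 9))
  out <- brightness_linearize(v, psf, 3)
  expect_equal(range(out), c(2, 2), tolerance = 1e-6)
  expect_true(all(out >= 0))

  # order 1: the root is the identity, so it equals RL-then-reconvolve
  set.seed(1)
  v2 <- array(runif(16 * 16 * 9), c(16, 16, 9))
  lin1 <- brightness_linearize(v2, psf, 1, iterations = 5)
  dec <- rl_deconvolve(v2, psf, 5)
  H <- axisim:::kernel_otf(axisim:::embed_centred(unclass(psf), dim(v2)))
  ref <- pmax(Re(stats::fft(stats::fft(dec) * H, inverse = TRUE)) /
                length(dec), 0)
  expect_equal(lin1, ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(brightness_linearize(v2, psf, 0), "order")
})

test_that("z flattening equalizes slice gains and keeps flat stacks flat", {
  set.seed(3)
  sl <- matrix(runif(16 * 16, 0.5, 1), 16)
  flat <- array(rep(sl, 8), c(16, 16, 8))
  expect_equal(z_flatten(flat), flat, tolerance = 1e-6, ignore_attr = TRUE)

  ramp <- array(0, c(16, 16, 3))
  for (k in 1:3) ramp[, , k] <- sl * c(1, 2, 4)[k]
  out <- z_flatten(ramp)
  m <- apply(out, 3, mean)
  expect_lt(diff(range(m)) / mean(m), 0.05)
  expect_true(all(out >= 0))
  expect_error(z_flatten(ramp[, , 1:2]), "3 slices")
})

test_that("FRC resolution finds constructed band limits and flags degeneracies", {
  img <- lowpass_noise(64, 0.9, 10)
  r_same <- frc_resolution(img, img, 5)
  expect_equal(as.numeric(r_same), 10)          # band edge = 2 px
  expect_equal(attr(r_same, "flag"), "unresolved-at-Nyquist")

  set.seed(11)
  n1 <- matrix(rnorm(128 * 128), 128); n2 <- matrix(rnorm(128 * 128), 128)
  r_noise <- frc_resolution(n1, n2, 1)
  curve <- attr(r_noise, "curve")
  tail_frc <- curve$frc[curve$freq_nyquist > 2 / 64]
  expect_lt(mean(abs(tail_frc)), 0.1)
  expect_lt(max(abs(tail_frc)), 0.35)

  sig <- lowpass_noise(64, 0.5, 12)
  a <- sig + 0.2 * sd(sig) * matrix(rnorm(64 * 64), 64)
  b <- sig + 0.2 * sd(sig) * matrix(rnorm(64 * 64), 64)
  r <- frc_resolution(a, b, 1)
  expect_equal(as.numeric(r), 4, tolerance = 0.15)
})

test_that("layer reconstruction upsamples, sharpens a bead beyond DL and zeroes pure noise", {
  gs <- c(24L, 24L, 24L)
  opt <- optical_config(lateral_spacing = 80, axial_spacing = 25,
                        grid_shape = gs)
  psf <- detection_psf(opt, shape = c(2L * gs[1] - 1L, gs[2], gs[3]))
  plan <- acquisition_plan(frames_per_layer = 40, z_step = 25, n_layers = 1)
  cfg <- recon_config(order = 3)

  lat_dl <- lat_c3 <- numeric(5)
  for (s in 1:5) {
    ph <- make_beads(1, diameter = 100, grid_shape = gs,
                     positions = matrix(c(11 * 80, 12 * 80,
                                          (axisim:::centre_index(24) - 1) * 25),
                                        1))
    acq <- acquire_stack(ph, plan, opt, mirror_config(), noise_model(),
                         seed = 30 + s)
    rl <- reconstruct_layer(acq$stack[, , , 1], psf, cfg)
    expect_equal(dim(rl$cumulant), c(48, 48))
    pk <- which(rl$dl == max(rl$dl), arr.ind = TRUE)[1, ]
    lat_dl[s] <- fwhm(rl$dl[pk[1], ], 80, rebound_frac = 0.5)
    pk2 <- which(rl$cumulant == max(rl$cumulant), arr.ind = TRUE)[1, ]
    lat_c3[s] <- fwhm(rl$cumulant[pk2[1], ], 40, rebound_frac = 0.5)
  }
  expect_true(all(lat_c3 < lat_dl))

  # background-only layer: cumulant centred on zero
  empty <- axisim:::new_phantom(array(0, c(24, 24, 24)), 80, 25)
  acq0 <- acquire_stack(empty, plan, opt, mirror_config(),
                        noise_model(read_noise_sd = 2), seed = 9)
  rl0 <- reconstruct_layer(acq0$stack[, , , 1], psf,
                           recon_config(order = 3))
  cum_signed <- rl0$cumulant * rl0$sign
  expect_lt(abs(mean(cum_signed)), 3 * sd(cum_signed))
})

test_that("integer-pixel input shifts shift the reconstruction by the upsampled amount", {
  gs <- c(16L, 24L, 24L)
  opt <- optical_config(lateral_spacing = 80, axial_spacing = 25,
                        grid_shape = gs)
  psf <- detection_psf(opt, shape = c(31L, 24L, 24L))
  ph <- make_beads(1, diameter = 150, grid_shape = gs,
                   positions = matrix(c(10 * 80, 13 * 80, 7 * 25), 1))
  plan <- acquisition_plan(frames_per_layer = 10, z_step = 25, n_layers = 1)
  acq <- acquire_stack(ph, plan, opt, mirror_config(), noise = NULL,
                       seed = 4)
  fr <- acq$stack[, , , 1]
  cfg <- recon_config(order = 2)
  base <- reconstruct_layer(fr, psf, cfg)$cumulant

  sh <- fr[c(22:24, 1:21), c(4:24, 1:3), , drop = FALSE]  # shift by (3, -3)
  out <- reconstruct_layer(sh, psf, cfg)$cumulant
  expected <- base[c((48 - 5):48, 1:(48 - 6)), c(7:48, 1:6)]
  expect_lt(max(abs(out - expected)) / max(base), 1e-6)
})

test_that("FRC-guided iteration choice honours its contracts", {
  gs <- c(20L, 24L, 24L)
  opt <- optical_config(lateral_spacing = 80, axial_spacing = 25,
                        grid_shape = gs)
  psf <- detection_psf(opt, shape = c(2L * gs[1] - 1L, gs[2], gs[3]))
  ph <- make_beads(1, diameter = 150, grid_shape = gs,
                   positions = matrix(c(11 * 80, 12 * 80, 9 * 25), 1))
  plan <- acquisition_plan(frames_per_layer = 8, z_step = 25, n_layers = 8)
  acq <- acquire_stack(ph, plan, opt, mirror_config(), noise = NULL,
                       seed = 6)
  layers <- lapply(1:8, function(z) acq$stack[, , , z])
  cfg <- recon_config(order = 2)

  expect_equal(as.integer(select_rl_iterations(layers, psf, cfg,
                                               candidates = 1)), 1L)

  # noise-free frames: resolution saturates, so the largest candidate wins
  pick <- select_rl_iterations(layers, psf, cfg, candidates = c(2, 5, 9))
  expect_equal(as.integer(pick), 9L)

  # the choice is the argmin of its own exhaustive evaluation table
  tab <- attr(pick, "frc_table")
  expect_equal(tab$iterations[which.min(tab$frc_resolution)],
               min(tab$iterations[tab$frc_resolution <=
                                    min(tab$frc_resolution) + 1e-12]))
})

test_that("reconstruction error decreases with the per-layer frame budget", {
  gs <- c(16L, 24L, 24L)
  opt <- optical_config(lateral_spacing = 80, axial_spacing = 25,
                        grid_shape = gs)
  psf <- detection_psf(opt, shape = c(31L, 24L, 24L))
  cfg <- recon_config(order = 2)
  budgets <- c(10, 25, 50, 100)
  ph <- make_beads(2, diameter = 120, grid_shape = gs,
                   positions = rbind(c(9 * 80, 9 * 80, 7 * 25),
                                     c(15 * 80, 16 * 80, 7 * 25)))
  errs <- matrix(NA_real_, 7, length(budgets))
  for (s in 1:7) {
    plan <- acquisition_plan(frames_per_layer = 320, z_step = 25,
                             n_layers = 1)
    acq <- acquire_stack(ph, plan, opt, mirror_config(), noise = NULL,
                         seed = 40 + s)
    fr <- acq$stack[, , , 1]
    ref <- reconstruct_layer(fr, psf, cfg)$cumulant
    ref <- ref / sqrt(sum(ref^2))
    for (b in seq_along(budgets)) {
      est <- reconstruct_layer(fr[, , seq_len(budgets[b]), drop = FALSE],
                               psf, cfg)$cumulant
      est <- est / sqrt(sum(est^2))
      errs[s, b] <- sqrt(sum((est - ref)^2))
    }
  }
  med <- apply(errs, 2, median)
  expect_true(all(diff(med) <= 0))
})
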
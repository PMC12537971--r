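# EMCCD noise model and the speckle-illuminated forward model.

test_that("EMCCD noise has Poisson-times-gain statistics and is seeded", {
  nm <- noise_model(em_gain = 10, read_noise_sd = 0, offset = 0,
                    excess_noise = FALSE)
  x <- apply_noise(rep(50, 1e5), nm, 1)
  expect_equal(var(x), nm$em_gain^2 * 50, tolerance = 0.05)
  expect_equal(mean(x), nm$em_gain * 50, tolerance = 0.02)

  # excess noise doubles the variance
  nme <- noise_model(em_gain = 10, read_noise_sd = 0, offset = 0,
                     excess_noise = TRUE)
  xe <- apply_noise(rep(50, 1e5), nme, 1)
  expect_equal(var(xe), 2 * nme$em_gain^2 * 50, tolerance = 0.07)

  # shot-noise scaling: relative error vanishes at large photon counts
  nb <- noise_model(photons_at_peak = 1e6, em_gain = 1, read_noise_sd = 0,
                    offset = 0, excess_noise = FALSE)
  y <- apply_noise(rep(1e6, 1e3), nb, 2)
  expect_lt(sqrt(mean((y / 1e6 - 1)^2)), 0.01)

  expect_identical(apply_noise(matrix(30, 8, 8), nm, 42),
                   apply_noise(matrix(30, 8, 8), nm, 42))
  expect_error(apply_noise(c(-1, 2), nm, 1), "non-negative")
})

test_that("frame rendering is linear and reproduces the in-focus PSF slice", {
  opt <- optical_config(lateral_spacing = 80, axial_spacing = 25,
                        grid_shape = c(33L, 32L, 32L))
  psf <- detection_psf(opt, c(65L, 32L, 32L))
  ph <- axisim:::new_phantom(array(0, c(32, 32, 33)), 80, 25)
  ph$density[17, 17, 17] <- 1

  fr <- render_frame(ph, NULL, psf, 17)
  sl <- psf[, , 33]
  expect_lt(sqrt(sum((fr / sum(fr) - sl / sum(sl))^2) / sum((sl / sum(sl))^2)),
            1e-6)

  ph2 <- ph; ph2$density <- 2 * ph$density
  fr2 <- render_frame(ph2, NULL, psf, 17)
  expect_lt(max(abs(fr2 - 2 * fr)) / max(fr), 1e-9)

  nm <- noise_model(offset = 100, read_noise_sd = 0)
  empty <- axisim:::new_phantom(array(0, c(32, 32, 33)), 80, 25)
  fr0 <- render_frame(empty, NULL, psf, 17, noise = nm, seed = 1)
  expect_true(all(fr0 == 100))
  expect_error(render_frame(ph, NULL, psf, 99), "focal_index")
})

test_that("acquisition has the planned shape, seeding and mirror-off equivalence", {
  gs <- c(12L, 24L, 24L)
  opt <- optical_config(lateral_spacing = 80, axial_spacing = 25,
                        grid_shape = gs)
  ph <- make_beads(1, diameter = 100, grid_shape = gs,
                   positions = matrix(c(11.5 * 80, 11.5 * 80, 5.5 * 25), 1))
  plan <- acquisition_plan(frames_per_layer = 4, z_step = 25, n_layers = 6)
  a1 <- acquire_stack(ph, plan, opt, mirror_config(TRUE, 1e5, 0, 0),
                      noise_model(), seed = 5)
  expect_equal(dim(a1$stack), c(24, 24, 4, 6))
  a2 <- acquire_stack(ph, plan, opt, mirror_config(enabled = FALSE),
                      noise_model(), seed = 5)
  expect_identical(as.vector(a1$stack), as.vector(a2$stack))
  a3 <- acquire_stack(ph, plan, opt, mirror_config(enabled = FALSE),
                      noise_model(), seed = 5)
  expect_identical(as.vector(a2$stack), as.vector(a3$stack))
})

test_that("within-layer speckle frames are mutually decorrelated", {
  # wide field: the correlation estimate averages ~1e3 speckle grains
  opt <- optical_config(grid_shape = c(4L, 128L, 128L), lateral_spacing = 80)
  planes <- lapply(1:12, function(k) {
    sp <- synthesize_speckle(sample_pupil(opt, 100 + k), opt,
                             mirror_config())
    as.vector(sp[, , 2])
  })
  cc <- c()
  for (i in 1:11) for (j in (i + 1):12)
    cc <- c(cc, cor(planes[[i]], planes[[j]]))
  expect_lt(mean(abs(cc)), 0.05)
})

test_that("in-focus emitters fluctuate more than 800 nm defocused ones", {
  gs <- c(72L, 24L, 24L)
  opt <- optical_config(lateral_spacing = 80, axial_spacing = 25,
                        grid_shape = gs)
  zf <- 36 * 25                                 # focal plane of the single layer
  ph <- make_beads(2, diameter = 100, grid_shape = gs,
                   positions = rbind(c(7 * 80, 7 * 80, zf),
                                     c(16 * 80, 16 * 80, zf + 800)))
  plan <- acquisition_plan(frames_per_layer = 50, z_step = 25, n_layers = 1)
  acq <- acquire_stack(ph, plan, opt, mirror_config(), noise_model(),
                       seed = 21)
  fr <- acq$stack[, , , 1]
  v_in <- var(fr[8, 8, ])
  v_out <- var(fr[17, 17, ])
  expect_gt(v_in, v_out)

  # and the DSI weight separates them even more strongly
  psf <- detection_psf(opt, shape = c(2L * gs[1] - 1L, gs[2], gs[3]))
  rl <- reconstruct_layer(fr, psf, recon_config(order = 2))
  expect_gt(rl$weight[8, 8] / rl$weight[17, 17], 1.5)
})
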
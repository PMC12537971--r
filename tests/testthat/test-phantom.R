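# Phantom generators: mass conservation, geometry, reproducibility.

test_that("bead phantoms conserve analytic mass and honour placement", {
  expect_equal(sum(make_beads(0, grid_shape = c(8L, 16L, 16L))$density), 0)

  gs <- c(48L, 64L, 64L)
  ph <- make_beads(5, diameter = 100, grid_shape = gs, seed = 3)
  expect_equal(sum(ph$density),
               5 * (4 / 3) * pi * 50^3 / (80^2 * 25), tolerance = 1e-6)
  expect_true(all(ph$density >= 0))

  # single centred bead: density centroid at the volume centre
  ctr <- c(31.5 * 80, 31.5 * 80, 23.5 * 25)
  p1 <- make_beads(1, diameter = 100, grid_shape = gs,
                   positions = matrix(ctr, 1))
  w <- which(p1$density > 0, arr.ind = TRUE)
  cen <- colSums(w * p1$density[w]) / sum(p1$density)
  expect_equal(unname(cen), c(32.5, 32.5, 24.5), tolerance = 1e-6)

  expect_identical(make_beads(4, grid_shape = gs, seed = 9)$density,
                   make_beads(4, grid_shape = gs, seed = 9)$density)
  expect_error(make_beads(50, grid_shape = c(8L, 16L, 16L),
                          min_spacing = 5000),
               "bounds too small")
})

test_that("hollow shells are empty inside, peak at the shell radius and conserve mass", {
  gs <- c(48L, 64L, 64L)
  ctr <- c(32 * 80, 32 * 80, 24 * 25)
  sh <- make_hollow_shells(1, outer_diameter = 800, shell_thickness = 120,
                           grid_shape = gs, positions = matrix(ctr, 1))
  expect_equal(sh$density[33, 33, 25], 0)
  expect_equal(sum(sh$density),
               (4 / 3) * pi * (400^3 - 280^3) / (80^2 * 25),
               tolerance = 0.02)
  # radial profile peaks at the shell mid-radius
  prof <- sh$density[33, , 25]
  r_nm <- abs((seq_len(64) - 33)) * 80
  peak_r <- r_nm[which.max(prof)]
  expect_lt(abs(peak_r - (800 - 120) / 2), 80)   # within one voxel
  expect_error(make_hollow_shells(1, outer_diameter = 200,
                                  shell_thickness = 150, grid_shape = gs),
               "shell_thickness")
})

test_that("filaments have uniform cross-section and constant linear density", {
  gs <- c(24L, 48L, 48L)
  st <- matrix(c(23 * 80, 4 * 80, 11 * 25), 1)
  dir <- matrix(c(0, 1, 0), 1)                # straight along x
  ph <- make_filaments(1, thickness = 160, curvature = 0, grid_shape = gs,
                       lateral_spacing = 80, axial_spacing = 25,
                       seed = 1, start = st, direction = dir)
  d <- ph$density
  xs <- 15:35                                 # interior of the tube's span
  ref <- d[, xs[1], ]
  for (x in xs[-1]) expect_lt(max(abs(d[, x, ] - ref)), 1e-6 * max(ref))
  # mass per unit length constant within 2%
  mass_per_col <- apply(d[, xs, ], 2, sum)
  expect_lt(diff(range(mass_per_col)) / mean(mass_per_col), 0.02)
  expect_identical(
    make_filaments(2, grid_shape = gs, seed = 5)$density,
    make_filaments(2, grid_shape = gs, seed = 5)$density)
})

test_that("moving particles travel at the requested speed and reproduce per seed", {
  mp0 <- make_moving_particles(3, speed = 0, n_frames = 10, seed = 2)
  expect_true(all(apply(mp0$positions, c(1, 3), function(p)
    diff(range(p))) == 0))

  mp <- make_moving_particles(4, speed = 80, frame_interval = 1,
                              n_frames = 20, seed = 2)
  disp <- apply(mp$positions, 1, function(p)
    sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
  expect_equal(as.vector(disp), rep(80, length(disp)), tolerance = 1e-6)

  expect_identical(make_moving_particles(4, n_frames = 15, seed = 8)$positions,
                   make_moving_particles(4, n_frames = 15, seed = 8)$positions)
})
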
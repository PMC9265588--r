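# Phase retrieval, Hilbert integration, spectral QC.

test_that("retrieval inverts the interference closed form", {
  cfg <- cfg_px()
  stk <- simulate_interferograms(delta_phi = matrix(pi / 4, 8, 8), gamma = 1,
                                 base_intensity = 1, config = cfg)
  g <- retrieve_phase_gradient(stk)
  expect_equal(g$delta_phi[4, 4, 1], pi / 4, tolerance = 1e-12)
  expect_equal(g$gamma[4, 4, 1], 1, tolerance = 1e-12)
  expect_equal(g$grad_x[4, 4, 1], pi / 4 / cfg$shear_um, tolerance = 1e-12)
})

test_that("zero fringe modulation is flagged, not inverted", {
  cfg <- cfg_px()
  stk <- simulate_interferograms(delta_phi = matrix(0.9, 8, 8), gamma = 0,
                                 base_intensity = 2, config = cfg)
  expect_warning(g <- retrieve_phase_gradient(stk), "modulation")
  expect_true(all(!g$modulation_ok))
  expect_true(all(g$delta_phi == 0))
})

test_that("noiseless simulate -> retrieve round trip is exact to 1e-10", {
  cfg <- cfg_px()
  set.seed(101)
  dphi <- matrix(runif(128 * 128, -pi + 0.01, pi - 0.01), 128, 128)
  stk <- simulate_interferograms(delta_phi = dphi, gamma = 1,
                                 base_intensity = 1, config = cfg)
  g <- retrieve_phase_gradient(stk)
  expect_lt(max(abs(g$delta_phi[, , 1] - dphi)), 1e-10)
})

test_that("a common additive offset on all four frames changes nothing", {
  cfg <- cfg_px()
  set.seed(7)
  dphi <- matrix(runif(64 * 64, -2, 2), 64, 64)
  stk <- simulate_interferograms(delta_phi = dphi, gamma = 1.3,
                                 base_intensity = 2, config = cfg)
  g0 <- retrieve_phase_gradient(stk)
  stk$frames <- stk$frames + 17.3   # incoherent scattering background
  g1 <- retrieve_phase_gradient(stk, tau_mod = g0$tau_mod)
  expect_lt(max(abs(g1$delta_phi - g0$delta_phi)), 1e-12)
  expect_lt(max(abs(g1$gamma - g0$gamma)), 1e-12)
})

test_that("retrieval error grows proportionally to noise_sd / gamma", {
  cfg <- cfg_px()
  set.seed(3)
  dphi <- matrix(runif(64 * 64, -1, 1), 64, 64)
  err <- vapply(c(0.02, 0.08), function(ns) {
    stk <- simulate_interferograms(delta_phi = dphi, gamma = 2,
                                   base_intensity = 3, config = cfg,
                                   noise_sd = ns, seed = 4)
    g <- retrieve_phase_gradient(stk, tau_mod = 0)
    sqrt(mean((g$delta_phi[, , 1] - dphi)^2))
  }, numeric(1))
  expect_gt(err[2], err[1])
  expect_equal(err[2] / err[1], 4, tolerance = 0.5)
})

test_that("malformed stacks raise format errors; all-zero stack warns", {
  cfg <- cfg_px()
  stk <- simulate_interferograms(delta_phi = matrix(0.2, 6, 6), config = cfg)
  bad <- stk
  bad$frames <- bad$frames[, , , 1:3, drop = FALSE]
  expect_error(retrieve_phase_gradient(bad), "frame")
  zero <- stk
  zero$frames[] <- 0
  expect_warning(g <- retrieve_phase_gradient(zero), "modulation")
  expect_true(all(!g$modulation_ok))
})

test_that("integrating a zero gradient gives a zero phase map", {
  ph <- integrate_gradient_hilbert(matrix(0, 32, 32), config = cfg_px())
  expect_true(all(abs(ph$phi) < 1e-14))
})

test_that("integration is linear and refuses 1-pixel-wide fields", {
  cfg <- cfg_px()
  set.seed(5)
  g <- matrix(rnorm(32 * 32), 32, 32)
  p1 <- integrate_gradient_hilbert(g, config = cfg)$phi
  p3 <- integrate_gradient_hilbert(3 * g, config = cfg)$phi
  expect_equal(p3, 3 * p1, tolerance = 1e-10)
  expect_error(integrate_gradient_hilbert(matrix(0, 32, 1), config = cfg),
               "1-pixel")
})

test_that("Gaussian bump is recovered from its analytic x-derivative", {
  n <- 256; s <- 10; A <- 1
  x <- matrix(rep(0:(n - 1), each = n), n); y <- t(x)
  cx <- (n - 1) / 2
  phi_true <- A * exp(-((x - cx)^2 + (y - cx)^2) / (2 * s^2))
  gx <- -(x - cx) / s^2 * phi_true
  rec <- integrate_gradient_hilbert(gx, config = cfg_px())$phi[, , 1]
  rec <- rec - mean(rec) + mean(phi_true)
  expect_lt(sqrt(mean((rec - phi_true)^2)), 0.01 * A)
})

test_that("numerical x-derivative of the integrated phase reproduces the gradient", {
  cfg <- cfg_small(seed = 6)
  ph <- make_phantom(c(96, 96, 14), n_cells = 2, mean_radius = 3,
                     config = cfg, seed = 6)
  phase0 <- project_phase(ph)
  stk <- simulate_interferograms(phase0, config = cfg)
  g <- retrieve_phase_gradient(stk)
  phi <- integrate_gradient_hilbert(g)$phi
  z <- 7
  # centered difference, interior pixels
  dx <- cfg$voxel_um[1]
  num <- (phi[, 3:96, z] - phi[, 1:94, z]) / (2 * dx)
  ref <- g$grad_x[, 2:95, z]
  rng <- diff(range(ref))
  expect_lt(sqrt(mean((num - ref)^2)), 0.02 * rng)
})

test_that("radial power spectrum localizes constant and sinusoidal images", {
  const <- radial_power_spectrum(matrix(4, 64, 64))
  expect_equal(const$power[1], 1)
  expect_true(all(const$power[-1] <= 1e-12))
  per <- 8
  img <- matrix(sin(2 * pi * (0:(63)) / per), 64, 64, byrow = TRUE)
  sp <- radial_power_spectrum(img, pixel_um = 1)
  peak <- sp$freq[which.max(sp$power)]
  binw <- diff(sp$freq[1:2])
  expect_lt(abs(peak - 1 / per), binw)
})

test_that("phase image keeps more high-frequency power than a raw DIC frame", {
  cfg <- cfg_small(seed = 9)
  ph <- make_phantom(c(96, 96, 12), n_cells = 3, mean_radius = 2.2,
                     config = cfg, seed = 9)
  phase0 <- project_phase(ph)
  # strong low-frequency incoherent clutter on the raw frames
  clutter <- glimquant:::gaussian_random_field(c(96, 96, 12), amplitude = 3,
                                               corr_um = 4,
                                               voxel_um = cfg$voxel_um)
  stk <- simulate_interferograms(phase0, config = cfg, base_intensity = 10,
                                 background = 10 + clutter, noise_sd = 0.05,
                                 seed = 2)
  phase <- integrate_gradient_hilbert(retrieve_phase_gradient(stk))
  z <- 6
  fcut <- (2 * cfg$na / cfg$wavelength) / 2
  hf_phase <- high_frequency_fraction(phase$phi[, , z], fcut, config = cfg)
  hf_dic <- high_frequency_fraction(stk$frames[, , z, 1], fcut, config = cfg)
  expect_gt(hf_phase, hf_dic)
})
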
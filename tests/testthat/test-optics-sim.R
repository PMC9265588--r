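# Forward model: phantoms, axial projection, four-frame interference.

test_that("acquisition config validates its invariants", {
  expect_error(acquisition_config(wavelength = -1), "wavelength")
  expect_error(acquisition_config(shear_um = 0), "shear_um")
  expect_error(acquisition_config(voxel_um = c(0.5, 0.5)), "voxel_um")
  expect_error(acquisition_config(phase_shifts = c(0, pi / 2, pi, 3 * pi / 2 + 1e-6)),
               "phase_shifts")
  expect_silent(acquisition_config(phase_shifts = c(0, pi / 2, pi, 3 * pi / 2) + 1e-14))
})

test_that("empty phantom is background texture only", {
  cfg <- cfg_small()
  ph <- make_phantom(c(24, 24, 10), n_cells = 0, config = cfg, seed = 3)
  expect_true(all(ph$labels == 0))
  expect_equal(nrow(ph$cell_truth), 0)
  expect_lt(abs(mean(ph$delta_n)), 1e-4)
  expect_equal(sd(ph$delta_n), 0.001, tolerance = 0.2)
})

test_that("phantom places the requested number of connected cells with exact truth", {
  cfg <- cfg_small()
  ph <- make_phantom(c(64, 64, 20), n_cells = 5, mean_radius = 2.5,
                     config = cfg, seed = 7)
  lab <- label_components(ph$labels > 0)
  expect_equal(attr(lab, "n_components"), 5L)
  # every positive label is one 26-connected component
  for (k in 1:5) {
    expect_equal(attr(label_components(ph$labels == k), "n_components"), 1L)
    expect_equal(ph$cell_truth$volume_um3[k],
                 sum(ph$labels == k) * prod(cfg$voxel_um))
  }
})

test_that("volume_scale shrinks ground-truth volume proportionally at constant mass", {
  cfg <- cfg_small()
  ph1 <- make_phantom(c(72, 72, 22), n_cells = 4, mean_radius = 2.8,
                      volume_scale = 1, config = cfg, seed = 5)
  ph2 <- make_phantom(c(72, 72, 22), n_cells = 4, mean_radius = 2.8,
                      volume_scale = 0.5, config = cfg, seed = 5)
  ratio <- mean(ph2$cell_truth$volume_um3) / mean(ph1$cell_truth$volume_um3)
  expect_equal(ratio, 0.5, tolerance = 0.1)   # one voxel-shell discretization
  mass_ratio <- mean(ph2$cell_truth$drymass_pg) / mean(ph1$cell_truth$drymass_pg)
  expect_equal(mass_ratio, 1, tolerance = 0.1)
})

test_that("impossible placement raises an error naming the achieved count", {
  cfg <- cfg_small()
  expect_error(
    make_phantom(c(16, 16, 8), n_cells = 10, mean_radius = 3, config = cfg,
                 seed = 1, max_tries = 50),
    "could only place [0-9]+ of 10")
})

test_that("phantom and stack are bit-identical under a fixed seed", {
  cfg <- cfg_small()
  ph1 <- make_phantom(c(32, 32, 12), n_cells = 2, mean_radius = 2.2,
                      config = cfg, seed = 11)
  ph2 <- make_phantom(c(32, 32, 12), n_cells = 2, mean_radius = 2.2,
                      config = cfg, seed = 11)
  expect_identical(ph1$delta_n, ph2$delta_n)
  expect_identical(ph1$labels, ph2$labels)
  s1 <- simulate_interferograms(project_phase(ph1), config = cfg,
                                noise_sd = 0.02, seed = 5)
  s2 <- simulate_interferograms(project_phase(ph2), config = cfg,
                                noise_sd = 0.02, seed = 5)
  expect_identical(s1$frames, s2$frames)
})

test_that("projection is zero for empty contrast and linear in contrast", {
  cfg <- cfg_small()
  dn <- array(0, dim = c(8, 8, 12))
  expect_true(all(project_phase(dn, cfg)$phi == 0))
  dn[3:6, 3:6, 4:9] <- 0.015
  p1 <- project_phase(dn, cfg)$phi
  p2 <- project_phase(2 * dn, cfg)$phi
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
})

test_that("slab projection matches the closed form and the convolution oracle", {
  # dz = 0.25 um so the 1.5 um kernel has interior support
  cfg <- acquisition_config(voxel_um = c(0.5, 0.5, 0.25), shear_um = 0.5,
                            wavelength = 0.78, axial_psf_um = 1.5)
  nz <- 60
  dn <- array(0, dim = c(4, 4, nz))
  dn[, , 15:45] <- 0.02   # slab much thicker than the kernel
  phi <- project_phase(dn, cfg)$phi
  central <- phi[2, 2, 30]
  expect_equal(central, 2 * pi * 0.02 * 1.5 / 0.78, tolerance = 1e-10)
  oracle <- project_column_oracle(dn[2, 2, ], 0.78, 1.5, 0.25)
  expect_equal(phi[2, 2, ], oracle, tolerance = 1e-10)
})

test_that("projection is invariant to axial translation of an interior slab", {
  cfg <- acquisition_config(voxel_um = c(0.5, 0.5, 0.25), shear_um = 0.5)
  nz <- 80
  mk <- function(z0) {
    dn <- array(0, dim = c(3, 3, nz)); dn[, , z0:(z0 + 20)] <- 0.01; dn
  }
  p1 <- project_phase(mk(20), cfg)$phi[2, 2, ]
  p2 <- project_phase(mk(32), cfg)$phi[2, 2, ]   # shifted by 12 voxels
  expect_equal(p1[25:35], p2[37:47], tolerance = 1e-12)
})

test_that("four-frame irradiances follow the interference closed form", {
  cfg <- cfg_px()
  # delta_phi = pi/4, gamma = 1, I = I' = 1
  stk <- simulate_interferograms(delta_phi = matrix(pi / 4, 6, 6), gamma = 1,
                                 base_intensity = 1, config = cfg)
  expect_equal(stk$frames[3, 3, 1, ],
               c(2 + sqrt(2), 2 - sqrt(2), 2 - sqrt(2), 2 + sqrt(2)),
               tolerance = 1e-12)
  # gamma = 0: no interference, all frames equal I + I'
  stk0 <- simulate_interferograms(delta_phi = matrix(0.7, 6, 6), gamma = 0,
                                  base_intensity = 1.5, config = cfg)
  expect_true(all(stk0$frames == 3))
  # delta_phi = 0: cosine extrema
  stke <- simulate_interferograms(delta_phi = matrix(0, 6, 6), gamma = 2,
                                  base_intensity = 3, config = cfg)
  expect_equal(unname(stke$frames[1, 1, 1, ]), c(10, 6, 2, 6), tolerance = 1e-12)
})

test_that("frame average over the four shifts equals I + I' exactly (noiseless)", {
  cfg <- cfg_small()
  ph <- make_phantom(c(40, 40, 10), n_cells = 1, mean_radius = 2.2,
                     config = cfg, seed = 4)
  stk <- simulate_interferograms(project_phase(ph), base_intensity = 5,
                                 config = cfg)
  avg <- apply(stk$frames, 1:3, mean)
  expect_equal(max(abs(avg - 10)), 0, tolerance = 1e-12)
})

test_that("sub-pixel shear is rejected with supersampling advice", {
  cfg <- acquisition_config(voxel_um = c(1, 1, 1), shear_um = 0.375)
  expect_error(shear_difference(matrix(0, 8, 8), cfg), "supersample")
})

test_that("intensities are clipped at zero and never negative under noise", {
  cfg <- cfg_px()
  stk <- simulate_interferograms(delta_phi = matrix(pi, 16, 16), gamma = 1,
                                 base_intensity = 1.01, config = cfg,
                                 noise_sd = 0.5, seed = 2)
  expect_true(all(stk$frames >= 0))
})

test_that("fluorescence channel colocalizes with the labels", {
  cfg <- cfg_small()
  ph <- make_phantom(c(48, 48, 16), n_cells = 2, mean_radius = 2.5,
                     config = cfg, seed = 8)
  fl <- fluorescence_channel(ph)
  expect_gt(mean(fl[ph$labels > 0]), 10 * mean(fl[ph$labels == 0]))
})
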
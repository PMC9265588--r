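# Trace voxelization, hull membership, phase refinement, fluorescence traces.

test_that("square traces on two slices voxelize to the expected cube", {
  sq <- cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))
  tr <- cell_trace("cube", list(list(z = 0, xy = sq), list(z = 9, xy = sq)))
  m <- voxelize_trace(tr, c(20, 20, 12), c(1, 1, 1))
  n <- sum(m$coarse)
  expect_equal(n, 1000)   # 10 x 10 x 10 axis-aligned hull, centers inclusive
  # against the closed-form membership oracle over all voxel centers
  idx <- which(m$coarse | TRUE, arr.ind = TRUE)
  ins <- apply(idx, 1, function(v) in_cube_oracle(c(v[2] - 1, v[1] - 1, v[3] - 1)))
  expect_equal(as.vector(m$coarse), as.vector(ins))
})

test_that("tetrahedron voxelization matches the closed-form half-space oracle", {
  tr <- cell_trace("tet", list(
    list(z = 0, xy = cbind(c(0, 10, 0), c(0, 0, 10))),
    list(z = 10, xy = cbind(c(0, 0.25, 0), c(0, 0, 0.25)))
  ))
  m <- voxelize_trace(tr, c(14, 14, 12), c(1, 1, 1))
  # oracle: the hull of these traces is contained in {x,y,z >= 0, x+y+z <= 10}
  # up to the small top facet; check every claimed-inside center against it
  idx <- which(m$coarse, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    expect_true(in_tetra_oracle(c(idx[r, 2] - 1, idx[r, 1] - 1, idx[r, 3] - 1)))
  }
  # count is the continuous volume (|det|/6 = 166.7) plus at most the
  # boundary-voxel shell that center-sampling can add
  vol <- 10^3 / 6
  shell <- sum(m$coarse) - sum({
    interior <- apply(idx, 1, function(v) {
      p <- c(v[2] - 1, v[1] - 1, v[3] - 1)
      all(p >= 1) && sum(p) <= 9
    })
    interior
  })
  expect_lt(abs(sum(m$coarse) - vol), shell + 1)
})

test_that("degenerate traces are rejected", {
  expect_error(cell_trace("t", list(list(z = 0, xy = cbind(0:3, c(0, 1, 0, 1))))),
               "2 distinct z")
  # all vertices on one plane after lifting -> zero enclosed volume
  # (constructed directly: the trace constructor already blocks single-z input)
  tr <- structure(list(cell_id = "flat", source = "manual", polygons = list(
    list(z = 2, xy = cbind(c(0, 5, 5), c(0, 0, 5))),
    list(z = 2, xy = cbind(c(1, 4, 4), c(1, 1, 4))))), class = "glim_trace")
  expect_error(voxelize_trace(tr, c(10, 10, 5), c(1, 1, 1)), "coplanar|degenerate")
  expect_error(cell_trace("bad", list(list(z = 0, xy = cbind(c(0, 1), c(0, 1))),
                                      list(z = 3, xy = cbind(c(0, 1), c(0, 1))))),
               "3 vertices")
  expect_error(cell_trace("cross", list(
    list(z = 0, xy = cbind(c(0, 4, 0, 4), c(0, 4, 4, 0))),
    list(z = 2, xy = cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))))),
    "self-intersecting")
})

test_that("out-of-grid vertices are an error", {
  sq <- cbind(c(0, 30, 30, 0), c(0, 0, 30, 30))
  tr <- cell_trace("big", list(list(z = 0, xy = sq), list(z = 4, xy = sq)))
  expect_error(voxelize_trace(tr, c(16, 16, 6), c(1, 1, 1)), "bounds")
})

test_that("hull membership satisfies convexity properties on random clouds", {
  set.seed(42)
  for (rep in 1:5) {
    pts <- matrix(rnorm(3 * 25), ncol = 3)
    hull <- glimquant:::convex_hull_3d(pts)
    # all generating points are inside
    expect_true(all(glimquant:::in_convex_hull(pts, hull)))
    # random convex combinations are inside
    w <- matrix(rexp(25 * 20), 20)
    w <- w / rowSums(w)
    expect_true(all(glimquant:::in_convex_hull(w %*% pts, hull)))
    # points strictly beyond the support plane of a random direction are outside
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    s <- max(pts %*% d)
    far <- t(vapply(1:10, function(i) rnorm(3) * 0.3 + d * (s + 0.5), numeric(3)))
    expect_true(all(!glimquant:::in_convex_hull(far, hull)))
  }
})

test_that("coarse mask volume is monotone under trace dilation", {
  sq <- function(a) cbind(c(-a, a, a, -a) + 8, c(-a, -a, a, a) + 8)
  tr1 <- cell_trace("s", list(list(z = 2, xy = sq(3)), list(z = 8, xy = sq(3))))
  tr2 <- cell_trace("s", list(list(z = 2, xy = sq(5)), list(z = 8, xy = sq(5))))
  m1 <- voxelize_trace(tr1, c(18, 18, 12), c(1, 1, 1))
  m2 <- voxelize_trace(tr2, c(18, 18, 12), c(1, 1, 1))
  expect_true(all(m2$coarse[m1$coarse]))
  expect_gt(sum(m2$coarse), sum(m1$coarse))
})

test_that("refinement removes near-zero phase, keeps negatives, and is idempotent", {
  sq <- cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))
  tr <- cell_trace("c", list(list(z = 0, xy = sq), list(z = 9, xy = sq)))
  m <- voxelize_trace(tr, c(12, 12, 10), c(1, 1, 1))
  phi <- array(0, dim = c(12, 12, 10))
  phi[, 1:5, ] <- 0.5            # half the cube columns carry signal
  phase <- glimquant:::new_phase(phi, c(1, 1, 1))
  r1 <- refine_mask(m, phase, tau = 0.05)
  expect_equal(sum(r1$refined), sum(m$coarse) / 2)
  expect_true(all(r1$refined[m$coarse & abs(phi) > 0.05]))
  # negative phase is retained
  phi2 <- phi; phi2[, 1:5, ] <- -0.5
  r2 <- refine_mask(m, glimquant:::new_phase(phi2, c(1, 1, 1)), tau = 0.05)
  expect_equal(sum(r2$refined), sum(m$coarse) / 2)
  # idempotent and never additive
  r3 <- refine_mask(r1, phase, tau = 0.05)
  expect_identical(r3$refined, r1$refined)
  expect_true(all(m$coarse[r1$refined]))
  # all below tau -> empty with warning
  expect_warning(r0 <- refine_mask(m, glimquant:::new_phase(phi * 0, c(1, 1, 1)),
                                   tau = 0.05), "removed every voxel")
  expect_equal(sum(r0$refined), 0)
})

test_that("blank fluorescence channel yields no traces", {
  expect_length(suppressMessages(traces_from_fluorescence(array(0, c(16, 16, 6)))), 0)
})

test_that("fluorescence traces recover the phantom somata", {
  cfg <- cohort_config(seed = 2)
  ph <- make_phantom(c(96, 96, 24), n_cells = 5, mean_radius = 3,
                     config = cfg, seed = 2)
  fl <- fluorescence_channel(ph)
  traces <- suppressMessages(traces_from_fluorescence(fl))
  expect_lte(length(traces), 5)   # touching somata may merge, never split up
  expect_equal(length(traces), 5) # default placement enforces a gap
  for (tr in traces) {
    zs <- vapply(tr$polygons, function(p) p$z, numeric(1))
    expect_gte(length(unique(zs)), 2)
  }
})

test_that("refined masks overlap the true cells well at default settings", {
  cfg <- cohort_config(seed = 13)
  ph <- make_phantom(c(108, 108, 27), n_cells = 5, mean_radius = 3.5,
                     config = cfg, seed = 13)
  stk <- simulate_interferograms(project_phase(ph), config = cfg,
                                 noise_sd = 0.05)
  phase <- integrate_gradient_hilbert(retrieve_phase_gradient(stk))
  traces <- suppressMessages(traces_from_fluorescence(fluorescence_channel(ph)))
  masks <- suppressWarnings(segment_cells(traces, phase))
  jac <- vapply(masks, function(m) {
    id <- match_mask_to_truth(m, ph$labels)
    tr <- ph$labels == id
    sum(m$refined & tr) / sum(m$refined | tr)
  }, numeric(1))
  expect_gte(median(jac), 0.8)
  expect_true(all(jac > 0.6))
})

test_that("median per-cell volume error stays within 10% across seeds", {
  cfg <- cohort_config()
  errs <- c()
  for (seed in 1:20) {
    ph <- make_phantom(c(96, 96, 27), n_cells = 3, mean_radius = 3.5,
                       config = cfg, seed = seed)
    stk <- simulate_interferograms(project_phase(ph), config = cfg,
                                   noise_sd = 0.05, seed = seed + 100)
    phase <- integrate_gradient_hilbert(retrieve_phase_gradient(stk))
    traces <- suppressMessages(traces_from_fluorescence(fluorescence_channel(ph)))
    masks <- suppressWarnings(segment_cells(traces, phase))
    for (m in masks) {
      id <- match_mask_to_truth(m, ph$labels)
      truth <- ph$cell_truth$volume_um3[ph$cell_truth$cell_id == id]
      errs <- c(errs, sum(m$refined) * prod(cfg$voxel_um) / truth - 1)
    }
  }
  expect_lte(median(abs(errs)), 0.10)
})
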
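# Synthetic refractive-index phantoms: ellipsoidal soma-like inclusions over a
# correlated scattering background, with exact per-cell ground truth.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# Zero-mean Gaussian random field with Gaussian correlation, given pointwise
# sd `amplitude` and correlation length `corr_um`.
gaussian_random_field <- function(shape, amplitude, corr_um, voxel_um) {
  if (amplitude <= 0) return(array(0, dim = shape))
  w <- array(stats::rnorm(prod(shape)), dim = shape)
  sig_vox <- corr_um / voxel_um
  f <- gauss_blur3(w, sig_vox)
  s <- stats::sd(f)
  if (s == 0) return(array(0, dim = shape))
  (f - mean(f)) / s * amplitude
}

#' Build a refractive-index phantom with known per-cell ground truth
#'
#' Places `n_cells` non-overlapping ellipsoidal soma-like inclusions of smooth
#' positive refractive-index contrast over a zero-mean correlated background
#' texture that stands in for tissue scattering. The label grid and the
#' `cell_truth` table provide exact ground truth for recovery tests: the true
#' volume of cell k is the count of voxels labelled k times the voxel volume,
#' and the true dry mass is the contrast integral over those voxels divided by
#' the refractive-index increment `alpha`.
#'
#' `volume_scale` shrinks every cell volume by that factor while scaling the
#' contrast up by its reciprocal, so ground-truth dry mass is (in expectation)
#' invariant — this is how day/night cohorts with volume regulation at
#' constant dry mass are generated.
#'
#' @param shape Integer length-3 grid size `(ny, nx, nz)` in voxels.
#' @param n_cells Number of cells to place (0 gives background only).
#' @param mean_radius Mean cell radius in micrometres.
#' @param volume_scale Multiplies target volumes (night groups use < 1).
#' @param config An [acquisition_config()].
#' @param radius Optional length-`n_cells` vector of radii (um), overriding
#'   `mean_radius`; applied before `volume_scale`.
#' @param delta_n Peak refractive-index contrast per cell (scalar or vector);
#'   negative values produce phase-depleted ("damaged") cells. Default 0.02.
#' @param n0 Background refractive index (default 1.337).
#' @param bg_amplitude Pointwise sd of the background contrast texture
#'   (default 0.001, a twentieth of the soma peak contrast; phase sd about
#'   12 mrad).
#' @param bg_corr_um Correlation length of the background texture in um
#'   (default 1.5).
#' @param edge_taper Fraction of the radius over which the contrast rolls off
#'   smoothly to zero (default 0.05, i.e. sub-voxel at the default sampling:
#'   somata are membrane-bound and the forward model applies no lateral PSF,
#'   so the optical boundary is sharp).
#' @param min_gap_um Minimum surface-to-surface distance between cells and to
#'   the grid border (default 1.5 um).
#' @param seed Integer seed; defaults to `config$seed`.
#' @param max_tries Total placement attempts before failing (default
#'   `200 * n_cells`).
#' @param alpha Refractive-index increment (mL/g) used to convert the
#'   ground-truth contrast integral to dry mass (default 0.2).
#'
#' @return A `glim_phantom`: list with `delta_n` and `labels` arrays
#'   (`[y, x, z]`), `n0`, `cell_truth` tibble
#'   (`cell_id`, `volume_um3`, `drymass_pg`, `radius_um`, `delta_n_max`),
#'   background parameters, and the config.
#' @examples
#' cfg <- acquisition_config(voxel_um = c(0.5, 0.5, 1), shear_um = 0.5)
#' ph <- make_phantom(c(48, 48, 20), n_cells = 2, mean_radius = 3,
#'                    config = cfg, seed = 7)
#' ph$cell_truth
#' @export
make_phantom <- function(shape, n_cells, mean_radius = 4, volume_scale = 1,
                         config = acquisition_config(),
                         radius = NULL, delta_n = 0.02, n0 = 1.337,
                         bg_amplitude = 0.001, bg_corr_um = 1.5,
                         edge_taper = 0.05, min_gap_um = 1.5,
                         seed = config$seed, max_tries = 200 * max(n_cells, 1),
                         alpha = 0.2) {
  stopifnot(length(shape) == 3, all(shape >= 1), n_cells >= 0, volume_scale > 0)
  config <- as_glim_config(config)
  vx <- config$voxel_um
  with_seed(seed, {
    dn_bg <- gaussian_random_field(shape, bg_amplitude, bg_corr_um, vx)
    labels <- array(0L, dim = shape)
    dn_cells <- array(0, dim = shape)
    truth <- list()

    if (n_cells > 0) {
      r0 <- if (is.null(radius)) rep_len(mean_radius, n_cells) else rep_len(radius, n_cells)
      r <- r0 * volume_scale^(1 / 3)
      dn_pk <- rep_len(delta_n, n_cells) / volume_scale
      # volume-preserving random ellipsoid axis ratios
      ax <- matrix(exp(stats::rnorm(3 * n_cells, 0, 0.08)), ncol = 3)
      ax <- ax / exp(rowMeans(log(ax)))

      # physical coordinates of voxel centers
      ys <- (seq_len(shape[1]) - 1) * vx[2]  # row index = y
      xs <- (seq_len(shape[2]) - 1) * vx[1]
      zs <- (seq_len(shape[3]) - 1) * vx[3]
      centers <- matrix(NA_real_, n_cells, 3)  # (y, x, z) um
      rmax <- r * apply(ax, 1, max)
      placed <- 0L
      tries <- 0L
      while (placed < n_cells && tries < max_tries) {
        tries <- tries + 1L
        i <- placed + 1L
        lo <- rmax[i] + min_gap_um
        hi <- c(max(ys), max(xs), max(zs)) - lo
        if (any(hi <= lo)) break
        cand <- c(stats::runif(1, lo, hi[1]), stats::runif(1, lo, hi[2]),
                  stats::runif(1, lo, hi[3]))
        ok <- TRUE
        if (placed > 0) {
          d <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
          ok <- all(d >= rmax[seq_len(placed)] + rmax[i] + min_gap_um)
        }
        if (ok) {
          centers[i, ] <- cand
          placed <- i
        }
      }
      if (placed < n_cells) {
        stop(sprintf("could only place %d of %d cells without overlap after %d tries",
                     placed, n_cells, tries), call. = FALSE)
      }

      for (i in seq_len(n_cells)) {
        # evaluate on the bounding box only
        ry <- r[i] * ax[i, 1]; rx <- r[i] * ax[i, 2]; rz <- r[i] * ax[i, 3]
        iy <- which(abs(ys - centers[i, 1]) <= ry)
        ix <- which(abs(xs - centers[i, 2]) <= rx)
        iz <- which(abs(zs - centers[i, 3]) <= rz)
        u <- sqrt(outer(outer(((ys[iy] - centers[i, 1]) / ry)^2,
                              ((xs[ix] - centers[i, 2]) / rx)^2, `+`),
                        ((zs[iz] - centers[i, 3]) / rz)^2, `+`))
        inside <- u < 1
        prof <- ifelse(u <= 1 - edge_taper, 1,
                       ifelse(u < 1, cos((u - (1 - edge_taper)) / edge_taper * pi / 2)^2, 0))
        sub <- dn_cells[iy, ix, iz, drop = FALSE]
        dn_cells[iy, ix, iz] <- sub + dn_pk[i] * prof
        lsub <- labels[iy, ix, iz, drop = FALSE]
        lsub[inside] <- i
        labels[iy, ix, iz] <- lsub
        dv <- prod(vx)
        truth[[i]] <- tibble::tibble(
          cell_id = i,
          volume_um3 = sum(inside) * dv,
          drymass_pg = sum(dn_pk[i] * prof[inside]) * dv / alpha_um3_per_pg(alpha),
          radius_um = r[i],
          delta_n_max = dn_pk[i]
        )
      }
    }

    cell_truth <- if (length(truth)) dplyr::bind_rows(truth) else {
      tibble::tibble(cell_id = integer(), volume_um3 = numeric(),
                     drymass_pg = numeric(), radius_um = numeric(),
                     delta_n_max = numeric())
    }
    structure(
      list(
        delta_n = dn_bg + dn_cells, delta_n_cells = dn_cells, labels = labels,
        n0 = n0, cell_truth = cell_truth,
        background = list(amplitude = bg_amplitude, corr_um = bg_corr_um),
        alpha = alpha, config = config, seed = seed
      ),
      class = "glim_phantom"
    )
  })
}

#' @export
print.glim_phantom <- function(x, ...) {
  d <- dim(x$delta_n)
  cat(sprintf("<glim_phantom> %d x %d x %d voxels, %d cells, n0 = %.3f\n",
              d[1], d[2], d[3], nrow(x$cell_truth), x$n0))
  invisible(x)
}

#' Fluorescence-like identification channel for a phantom
#'
#' Emulates a colocalized astrocyte label (SR101-style): the cell support,
#' blurred and corrupted by Poisson shot noise. Used to derive coarse traces
#' when no manual annotation exists. Photophysics is not modelled.
#'
#' @param phantom A `glim_phantom`.
#' @param blur_um Isotropic Gaussian blur sigma in um (default 0.5).
#' @param photons Expected in-cell photon count (default 50).
#' @param background Expected background photon count (default 2).
#' @param seed Seed for the shot noise; defaults to `phantom$seed + 1`.
#' @return A 3D array `[y, x, z]` of photon counts.
#' @export
fluorescence_channel <- function(phantom, blur_um = 0.5, photons = 50,
                                 background = 2, seed = phantom$seed + 1) {
  vx <- phantom$config$voxel_um
  supp <- array(as.numeric(phantom$labels > 0), dim = dim(phantom$labels))
  lam <- gauss_blur3(supp, blur_um / vx[c(2, 1, 3)]) * photons + background
  lam[lam < 0] <- 0
  with_seed(seed, array(stats::rpois(length(lam), lam), dim = dim(lam)))
}

# Triangular axial sectioning weights: taps c_k (um) at z-offsets k*dz within
# half the kernel full width, scaled so sum(c_k) = axial_psf. A column of
# constant contrast thicker than the kernel then yields
# phi = (2*pi/lambda) * delta_n * axial_psf.
axial_kernel <- function(axial_psf_um, dz) {
  half <- axial_psf_um / 2
  k <- seq(-floor(half / dz), floor(half / dz))
  t <- 1 - abs(k * dz) / half
  t[t < 0] <- 0
  if (sum(t) == 0) { k <- 0L; t <- 1 }
  list(offsets = k, weights = t / sum(t) * axial_psf_um)
}

#' Project a phantom to its quantitative phase tomogram
#'
#' Optical-sectioning surrogate: each focal slice reports the phase of an
#' effective slab of thickness `axial_psf_um`, i.e.
#' \eqn{\phi(x,y,z) = (2\pi/\lambda)\sum_{z'} \delta n(x,y,z')\, c(z-z')}
#' with triangular weights \eqn{c} summing to the axial PSF width. This is the
#' phase the reconstruction is expected to recover, and it inverts exactly to
#' the contrast used by dry-mass densitometry (see [compute_dry_mass()]).
#'
#' @param phantom A `glim_phantom`, or any 3D contrast array.
#' @param config An [acquisition_config()]; defaults to the phantom's.
#' @return A `glim_phase` object: `phi` array (rad), `voxel_um`, provenance.
#' @export
project_phase <- function(phantom, config = NULL) {
  if (inherits(phantom, "glim_phantom")) {
    dn <- phantom$delta_n
    config <- as_glim_config(config %||% phantom$config)
  } else {
    dn <- phantom
    if (is.null(config)) stop("`config` is required when passing a bare array")
    config <- as_glim_config(config)
  }
  stopifnot(length(dim(dn)) == 3)
  kern <- axial_kernel(config$axial_psf_um, config$voxel_um[3])
  d <- dim(dn)
  phi <- array(0, dim = d)
  for (j in seq_along(kern$offsets)) {
    k <- kern$offsets[j]
    src <- seq_len(d[3]) + k
    valid <- src >= 1 & src <= d[3]
    phi[, , valid] <- phi[, , valid] +
      kern$weights[j] * dn[, , src[valid], drop = FALSE]
  }
  phi <- phi * (2 * pi / config$wavelength)
  new_phase(phi, config$voxel_um,
            provenance = list(source = "projection",
                              axial_psf_um = config$axial_psf_um,
                              wavelength = config$wavelength))
}

new_phase <- function(phi, voxel_um, provenance = list()) {
  structure(list(phi = phi, voxel_um = as.numeric(voxel_um),
                 provenance = provenance),
            class = "glim_phase")
}

#' @export
print.glim_phase <- function(x, ...) {
  d <- dim(x$phi)
  if (length(d) == 2) d <- c(d, 1)
  cat(sprintf("<glim_phase> %d x %d x %d, phase range [%.3f, %.3f] rad\n",
              d[1], d[2], d[3], min(x$phi), max(x$phi)))
  invisible(x)
}
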
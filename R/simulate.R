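# Forward interference model: renders the four phase-shifted irradiance
# frames I_n = I + I' + 2*gamma*cos(delta_phi + eps_n) that the retrieval
# module consumes.

#' Sheared phase difference
#'
#' Computes \eqn{\Delta\phi(r) = \phi(r + \delta) - \phi(r)} by shifting the
#' phase map along x by the configured shear (edge pixels replicate; fractional
#' shears use Fourier interpolation). This is the quantity the four-frame
#' interference encodes, and dividing it by the shear approximates the lateral
#' phase gradient.
#'
#' @param phase A `glim_phase`, or a matrix / 3D array of phase (rad).
#' @param config An [acquisition_config()].
#' @return Array of the same shape as the input phase.
#' @export
shear_difference <- function(phase, config) {
  config <- as_glim_config(config)
  phi <- if (inherits(phase, "glim_phase")) phase$phi else phase
  s <- shear_px(config)
  one <- function(m) shift_x(m, s) - m
  if (length(dim(phi)) == 3) {
    out <- array(0, dim = dim(phi))
    for (z in seq_len(dim(phi)[3])) out[, , z] <- one(phi[, , z])
    out
  } else {
    one(as.matrix(phi))
  }
}

#' Simulate a four-frame phase-shifted interferogram stack
#'
#' Coherent superposition of the two sheared fields at the detector: for each
#' retarder offset \eqn{\epsilon_n \in \{0, \pi/2, \pi, 3\pi/2\}},
#' \deqn{I_n = I + I' + 2\gamma \cos(\Delta\phi + \epsilon_n)}
#' with \eqn{I = I'} = `base_intensity` and \eqn{\gamma} the mutual intensity
#' (fringe modulation). An incoherent scattering background adds a common
#' offset to all four frames; it carries no fringe modulation and is rejected
#' exactly by the retrieval. Optional additive Gaussian read noise; negative
#' intensities are clipped at zero.
#'
#' @param phase A `glim_phase` (2D or 3D) giving \eqn{\phi}.
#' @param gamma Mutual intensity: scalar or grid, `>= 0`. Default
#'   `0.9 * base_intensity`.
#' @param base_intensity Scalar or grid, `> 0`. Default 10.
#' @param config An [acquisition_config()].
#' @param noise_sd Additive Gaussian noise sd in intensity units (default 0).
#' @param background Incoherent background intensity: scalar or grid added to
#'   every frame (default 0).
#' @param delta_phi Optional precomputed \eqn{\Delta\phi} array; bypasses the
#'   shear of `phase` (used for oracle tests).
#' @param seed Seed for the noise; defaults to `config$seed + 2`.
#' @return A `glim_stack`: list with `frames` array `[y, x, z, 4]`
#'   (non-negative intensities) and `config`.
#' @examples
#' cfg <- acquisition_config(voxel_um = c(0.5, 0.5, 1), shear_um = 0.5)
#' stk <- simulate_interferograms(delta_phi = matrix(pi / 4, 8, 8),
#'                                gamma = 1, base_intensity = 1, config = cfg)
#' stk$frames[1, 1, 1, ]  # (2 + sqrt(2), 2 - sqrt(2), 2 - sqrt(2), 2 + sqrt(2))
#' @export
simulate_interferograms <- function(phase = NULL, gamma = NULL, base_intensity = 10,
                                    config = acquisition_config(),
                                    noise_sd = 0, background = 0,
                                    delta_phi = NULL,
                                    seed = config$seed + 2) {
  config <- as_glim_config(config)
  if (is.null(gamma)) gamma <- 0.9 * base_intensity
  if (any(gamma < 0)) stop("`gamma` must be non-negative", call. = FALSE)
  if (any(base_intensity <= 0)) stop("`base_intensity` must be positive", call. = FALSE)
  if (is.null(phase) && is.null(delta_phi)) {
    stop("provide either `phase` or `delta_phi`", call. = FALSE)
  }
  dphi <- if (is.null(delta_phi)) shear_difference(phase, config) else delta_phi
  d <- dim(dphi)
  if (length(d) == 2) { dim(dphi) <- c(d, 1); d <- dim(dphi) }
  frames <- array(0, dim = c(d, 4))
  for (n in 1:4) {
    frames[, , , n] <- 2 * base_intensity + background +
      2 * gamma * cos(dphi + config$phase_shifts[n])
  }
  if (noise_sd > 0) {
    frames <- with_seed(seed, frames + stats::rnorm(length(frames), 0, noise_sd))
  }
  frames[frames < 0] <- 0
  structure(list(frames = frames, config = config), class = "glim_stack")
}

#' @export
print.glim_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<glim_stack> %d x %d, %d plane(s) x 4 frames, intensity [%.2f, %.2f]\n",
              d[1], d[2], d[3], min(x$frames), max(x$frames)))
  invisible(x)
}
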
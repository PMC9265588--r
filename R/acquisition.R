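#' Acquisition configuration
#'
#' Bundles the optical and sampling parameters shared by the simulator and the
#' reconstruction: illumination wavelength, lateral shear between the two
#' orthogonally polarized beams, voxel size, axial sectioning width, and the
#' four phase-shift offsets applied by the variable retarder.
#'
#' @param wavelength Illumination wavelength in micrometres. Default 0.780
#'   (near-IR LED, chosen to limit scattering in thick tissue).
#' @param shear_um Lateral shear \eqn{\delta_x} between the two beams in
#'   micrometres, nominally about half the point-spread-function diameter.
#'   Default 0.375 (half of the 0.75 um lateral resolution).
#' @param voxel_um Numeric length-3 vector `(dx, dy, dz)` in micrometres.
#' @param axial_psf_um Full width of the axial sectioning response in
#'   micrometres (default 1.5, the axial resolution of the system).
#' @param phase_shifts The four retarder offsets \eqn{\epsilon_n} in radians;
#'   must equal `c(0, pi/2, pi, 3*pi/2)` to numerical precision.
#' @param na Numerical aperture used for the diffraction-limit reference
#'   frequency in spectral QC (default 0.75).
#' @param grad_sign `+1` or `-1`; flips the sign convention of the retrieved
#'   gradient for datasets whose shear orientation is reversed.
#' @param seed Integer seed used by simulation routines that take this
#'   config (can be overridden per call).
#'
#' @return An object of class `glim_config` (a named list).
#' @examples
#' cfg <- acquisition_config(voxel_um = c(0.375, 0.375, 1))
#' cfg$shear_um
#' @export
acquisition_config <- function(wavelength = 0.780,
                               shear_um = 0.375,
                               voxel_um = c(0.375, 0.375, 1.0),
                               axial_psf_um = 1.5,
                               phase_shifts = c(0, pi / 2, pi, 3 * pi / 2),
                               na = 0.75,
                               grad_sign = 1,
                               seed = 1L) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1, wavelength > 0)
  stopifnot(is.numeric(shear_um), length(shear_um) == 1, shear_um > 0)
  stopifnot(is.numeric(voxel_um), length(voxel_um) == 3, all(voxel_um > 0))
  stopifnot(is.numeric(axial_psf_um), length(axial_psf_um) == 1, axial_psf_um > 0)
  if (length(phase_shifts) != 4 ||
      any(abs(phase_shifts - c(0, pi / 2, pi, 3 * pi / 2)) > 1e-12)) {
    stop("`phase_shifts` must be exactly c(0, pi/2, pi, 3*pi/2)", call. = FALSE)
  }
  stopifnot(grad_sign %in% c(-1, 1))
  structure(
    list(
      wavelength = wavelength, shear_um = shear_um,
      voxel_um = as.numeric(voxel_um), axial_psf_um = axial_psf_um,
      phase_shifts = as.numeric(phase_shifts), na = na,
      grad_sign = grad_sign, seed = as.integer(seed)
    ),
    class = "glim_config"
  )
}

#' @export
print.glim_config <- function(x, ...) {
  cat("<glim_config>\n")
  cat(sprintf("  wavelength: %.3f um   shear: %.3f um   axial PSF: %.2f um\n",
              x$wavelength, x$shear_um, x$axial_psf_um))
  cat(sprintf("  voxel: (%.3f, %.3f, %.3f) um   NA: %.2f   seed: %d\n",
              x$voxel_um[1], x$voxel_um[2], x$voxel_um[3], x$na, x$seed))
  invisible(x)
}

# shear expressed in pixels of the x axis; the 4-frame model is only valid
# when the shear is resolvable on the grid.
shear_px <- function(config) {
  s <- config$shear_um / config$voxel_um[1]
  if (s < 1 - 1e-9) {
    stop(sprintf(
      paste0("shear of %.3f um is %.2f pixels at dx = %.3f um; ",
             "supersample the grid so the shear spans at least one pixel"),
      config$shear_um, s, config$voxel_um[1]), call. = FALSE)
  }
  s
}

as_glim_config <- function(x) {
  if (inherits(x, "glim_config")) return(x)
  do.call(acquisition_config, x)
}
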
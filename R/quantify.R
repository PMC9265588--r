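# Per-cell volume, dry mass, density, and damaged-cell classification.
#
# Dry mass follows from the scattering-potential integral
#   m = 1/(2 n0 alpha) * integral chi(r) d^3r,   chi = n^2 - n0^2,
# which for small contrast (chi ~ 2 n0 (n - n0)) reduces to
#   m = (1/alpha) * integral delta_n(r) d^3r.
# The sectioned phase reports an effective slab of thickness zeta (the axial
# PSF width), so the per-voxel contrast is delta_n = phi * lambda / (2 pi zeta);
# dividing by zeta is what prevents a physical voxel from being counted once
# per z-slice across the PSF support.

#' Cell volume from a refined mask
#'
#' The number of refined voxels times the voxel volume. An empty mask warns
#' and yields 0.
#'
#' @param mask A refined `glim_mask`.
#' @param use `"refined"` (default) or `"coarse"`.
#' @return Volume in um^3.
#' @export
compute_volume <- function(mask, use = c("refined", "coarse")) {
  use <- match.arg(use)
  stopifnot(inherits(mask, "glim_mask"))
  m <- mask[[use]]
  if (use == "refined" && is.null(m)) stop("mask has no refined component; run refine_mask()", call. = FALSE)
  n <- sum(m)
  if (n == 0) warning(sprintf("cell %s: empty %s mask, volume 0", mask$cell_id, use))
  n * prod(mask$voxel_um)
}

#' Cell dry mass from a refined mask and a phase tomogram
#'
#' Converts each in-mask voxel's phase to refractive contrast
#' \eqn{\delta n = \phi \lambda / (2\pi\zeta)} with \eqn{\zeta} the axial
#' normalization (default the axial PSF width), sums the contrast over the
#' mask, and divides by the refractive-index increment \eqn{\alpha}:
#' \deqn{m = \frac{1}{\alpha} \sum_{r \in mask} \delta n(r)\, dx\, dy\, dz.}
#' Negative totals are allowed and flag damaged, phase-depleted cells. The
#' alternative `axial_norm = "slice2d"` sums \eqn{\phi \lambda/(2\pi\alpha)}
#' over the single best-focus slice (classic 2D QPI densitometry).
#'
#' @param mask A refined `glim_mask`.
#' @param phase A `glim_phase` on the same grid.
#' @param alpha Refractive-index increment in mL/g (default 0.2).
#' @param config Optional [acquisition_config()]; supplies wavelength and
#'   axial PSF if the phase provenance lacks them.
#' @param axial_norm `"psf"` (default; \eqn{\zeta} = axial PSF width) or
#'   `"slice2d"`.
#' @param use Mask component to sum over (default `"refined"`).
#' @return Dry mass in pg.
#' @export
compute_dry_mass <- function(mask, phase, alpha = 0.2, config = NULL,
                             axial_norm = c("psf", "slice2d"),
                             use = c("refined", "coarse")) {
  axial_norm <- match.arg(axial_norm)
  use <- match.arg(use)
  stopifnot(inherits(mask, "glim_mask"), inherits(phase, "glim_phase"),
            alpha > 0)
  if (!identical(dim(phase$phi), dim(mask$coarse))) {
    stop("mask and phase grids do not match", call. = FALSE)
  }
  lambda <- phase$provenance$wavelength %||% (if (!is.null(config)) as_glim_config(config)$wavelength else NULL)
  zeta <- phase$provenance$axial_psf_um %||% (if (!is.null(config)) as_glim_config(config)$axial_psf_um else NULL)
  if (is.null(lambda) || is.null(zeta)) {
    stop("wavelength / axial PSF metadata missing: pass `config`", call. = FALSE)
  }
  m <- mask[[use]]
  if (is.null(m)) stop(sprintf("mask has no %s component", use), call. = FALSE)
  vx <- phase$voxel_um
  if (axial_norm == "psf") {
    dn <- phase$phi[m] * lambda / (2 * pi * zeta)
    sum(dn) * prod(vx) / alpha_um3_per_pg(alpha)
  } else {
    zcount <- apply(m, 3, sum)
    if (all(zcount == 0)) return(0)
    zbest <- which.max(zcount)
    sl <- m[, , zbest]
    sum(phase$phi[, , zbest][sl]) * lambda / (2 * pi) * vx[1] * vx[2] /
      alpha_um3_per_pg(alpha)
  }
}

# Background re-referencing: per-slice median phase outside all coarse masks.
# The integrated tomogram is normalized to zero mean per slice, which drags
# the true zero level slightly negative wherever cells occupy the field; the
# in-mask sums are unbiased once the empty-tissue level is subtracted.
rereference_background <- function(phase, masks) {
  phi <- phase$phi
  outside <- array(TRUE, dim = dim(phi))
  for (m in masks) outside[m$coarse] <- FALSE
  for (z in seq_len(dim(phi)[3])) {
    o <- outside[, , z]
    if (any(o)) phi[, , z] <- phi[, , z] - stats::median(phi[, , z][o])
  }
  phase$phi <- phi
  phase$provenance$background_rereferenced <- TRUE
  phase
}

#' Build the per-cell record table
#'
#' One row per non-empty refined mask, joined to its `(animal_id, group)`
#' metadata. Before summing, the tomogram's zero level is re-anchored to the
#' per-slice median phase outside all coarse masks. Cells whose refined mask
#' is empty are dropped with a message; a `cell_id` missing from the groups
#' table is an error. Rows are ordered by `(animal_id, cell_id)`.
#'
#' @param masks List of refined `glim_mask` objects.
#' @param phase The `glim_phase` tomogram they were segmented on.
#' @param groups Data frame with columns `cell_id`, `animal_id`, `group`
#'   (values `"day"`/`"night"`), optionally `Vm_mV`, `Rin_MOhm` (carried
#'   through untouched).
#' @param alpha Refractive-index increment in mL/g (default 0.2).
#' @param config Optional config for mass metadata (see [compute_dry_mass()]).
#' @param axial_norm Passed to [compute_dry_mass()].
#' @param rereference Re-anchor the background level first (default TRUE).
#' @return A tibble with columns `cell_id`, `animal_id`, `group`,
#'   `volume_um3`, `drymass_pg`, `density_g_per_L`, `damaged`, `n_voxels`,
#'   `n_voxels_coarse`, `mean_phase_rad`, plus any pass-through columns.
#' @export
build_cell_table <- function(masks, phase, groups, alpha = 0.2, config = NULL,
                             axial_norm = "psf", rereference = TRUE) {
  stopifnot(inherits(phase, "glim_phase"), is.data.frame(groups))
  req <- c("cell_id", "animal_id", "group")
  if (!all(req %in% names(groups))) {
    stop("`groups` needs columns cell_id, animal_id, group", call. = FALSE)
  }
  ids <- vapply(masks, function(m) as.character(m$cell_id), character(1))
  missing <- setdiff(ids, as.character(groups$cell_id))
  if (length(missing)) {
    stop(sprintf("no (animal_id, group) row for cell(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (rereference) phase <- rereference_background(phase, masks)

  rows <- list()
  for (m in masks) {
    if (is.null(m$refined) || !any(m$refined)) {
      message(sprintf("cell %s excluded: empty refined mask", m$cell_id))
      next
    }
    vol <- compute_volume(m)
    mass <- compute_dry_mass(m, phase, alpha = alpha, config = config,
                             axial_norm = axial_norm)
    g <- groups[match(as.character(m$cell_id), as.character(groups$cell_id)), ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = g$cell_id, animal_id = g$animal_id,
      group = as.character(g$group),
      volume_um3 = vol, drymass_pg = mass,
      density_g_per_L = if (vol > 0) mass / vol * PG_PER_UM3_TO_G_PER_L else NA_real_,
      damaged = mass < 0,
      n_voxels = sum(m$refined), n_voxels_coarse = sum(m$coarse),
      mean_phase_rad = mean(phase$phi[m$refined]),
      Vm_mV = if ("Vm_mV" %in% names(g)) g$Vm_mV else NA_real_,
      Rin_MOhm = if ("Rin_MOhm" %in% names(g)) g$Rin_MOhm else NA_real_
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(cell_id = character(), animal_id = character(),
                          group = character(), volume_um3 = numeric(),
                          drymass_pg = numeric(), density_g_per_L = numeric(),
                          damaged = logical(), n_voxels = integer(),
                          n_voxels_coarse = integer(), mean_phase_rad = numeric(),
                          Vm_mV = numeric(), Rin_MOhm = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$animal_id, .data$cell_id)
}
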
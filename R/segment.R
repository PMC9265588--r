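# Sparse per-slice ROI traces -> coarse Delaunay-hull voxel masks -> phase
# refined masks.

#' Construct a cell trace
#'
#' A sparse 3D annotation of one cell: simple polygons drawn on a small number
#' of z-slices, as produced by manual ImageJ tracing or derived from a
#' fluorescence identification channel.
#'
#' @param cell_id Identifier (integer or character).
#' @param polygons List of `list(z = <0-based slice index>, xy = <k x 2 matrix
#'   of (x, y) pixel vertices>)`.
#' @param source `"manual"` or `"fluorescence"`.
#' @return A `glim_trace`.
#' @export
cell_trace <- function(cell_id, polygons, source = c("manual", "fluorescence")) {
  source <- match.arg(source)
  if (length(polygons) < 1) stop("trace needs at least one polygon", call. = FALSE)
  zs <- vapply(polygons, function(p) as.numeric(p$z), numeric(1))
  if (length(unique(zs)) < 2) {
    stop("trace must span at least 2 distinct z-slices (zero-thickness input)",
         call. = FALSE)
  }
  for (p in polygons) {
    xy <- as.matrix(p$xy)
    if (nrow(xy) < 3) stop("each polygon needs at least 3 vertices", call. = FALSE)
    if (!polygon_is_simple(xy)) {
      stop(sprintf("self-intersecting polygon in trace %s at z = %s",
                   cell_id, p$z), call. = FALSE)
    }
  }
  structure(list(cell_id = cell_id, polygons = polygons, source = source),
            class = "glim_trace")
}

# O(k^2) segment-crossing check; adjacent edges share endpoints and are
# exempt. Adequate for the small polygons produced by tracing.
polygon_is_simple <- function(xy) {
  k <- nrow(xy)
  if (k < 4) return(TRUE)
  seg <- cbind(xy, xy[c(2:k, 1), ])
  crosses <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(k - 2)) {
    for (j in (i + 2):k) {
      if (i == 1 && j == k) next
      if (crosses(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.glim_trace <- function(x, ...) {
  zs <- vapply(x$polygons, function(p) p$z, numeric(1))
  cat(sprintf("<glim_trace> cell %s (%s), %d polygons on z = %s\n",
              x$cell_id, x$source, length(x$polygons),
              paste(sort(unique(zs)), collapse = ", ")))
  invisible(x)
}

#' Voxelize a trace into a coarse 3D mask
#'
#' Lifts every polygon vertex to physical coordinates (respecting z
#' anisotropy), forms the Delaunay/convex hull of the point cloud, and marks
#' a voxel as inside iff its center lies within the hull (boundary counts as
#' inside). This reproduces the point-in-tetrahedral-mesh test used for
#' manual 3D annotation; concavities cannot be represented and traces are
#' expected to outline the cell body.
#'
#' @param trace A [cell_trace()].
#' @param grid_shape Length-3 `(ny, nx, nz)` of the target grid.
#' @param voxel_um Length-3 `(dx, dy, dz)` in um.
#' @return A `glim_mask` with the `coarse` logical array filled and `refined`
#'   unset (`NULL`); see [refine_mask()].
#' @export
voxelize_trace <- function(trace, grid_shape, voxel_um) {
  stopifnot(inherits(trace, "glim_trace"), length(grid_shape) == 3,
            length(voxel_um) == 3, all(voxel_um > 0))
  pts <- do.call(rbind, lapply(trace$polygons, function(p) {
    xy <- as.matrix(p$xy)
    cbind(xy[, 1] * voxel_um[1], xy[, 2] * voxel_um[2], p$z * voxel_um[3])
  }))
  lim <- (grid_shape[c(2, 1, 3)] - 1)  # x, y, z in pixel units
  px <- pts / rep(voxel_um, each = nrow(pts))
  if (any(px < -0.5 - 1e-9) || any(px > rep(lim, each = nrow(px)) + 0.5 + 1e-9)) {
    stop("trace vertices fall outside the grid bounds", call. = FALSE)
  }
  hull <- convex_hull_3d(pts)

  # candidate voxel centers inside the hull bounding box
  rng <- apply(hull$points, 2, range)
  ix <- seq(max(0, floor(rng[1, 1] / voxel_um[1])),
            min(lim[1], ceiling(rng[2, 1] / voxel_um[1])))
  iy <- seq(max(0, floor(rng[1, 2] / voxel_um[2])),
            min(lim[2], ceiling(rng[2, 2] / voxel_um[2])))
  iz <- seq(max(0, floor(rng[1, 3] / voxel_um[3])),
            min(lim[3], ceiling(rng[2, 3] / voxel_um[3])))
  grid <- as.matrix(expand.grid(x = ix * voxel_um[1], y = iy * voxel_um[2],
                                z = iz * voxel_um[3]))
  inside <- in_convex_hull(grid, hull)

  coarse <- array(FALSE, dim = grid_shape)
  if (any(inside)) {
    idx <- as.matrix(expand.grid(x = ix, y = iy, z = iz))[inside, , drop = FALSE]
    coarse[cbind(idx[, 2] + 1L, idx[, 1] + 1L, idx[, 3] + 1L)] <- TRUE
  }
  structure(list(cell_id = trace$cell_id, coarse = coarse, refined = NULL,
                 voxel_um = as.numeric(voxel_um), source = trace$source),
            class = "glim_mask")
}

#' @export
print.glim_mask <- function(x, ...) {
  cat(sprintf("<glim_mask> cell %s: %d coarse, %s refined voxels\n",
              x$cell_id, sum(x$coarse),
              if (is.null(x$refined)) "un-" else sum(x$refined)))
  invisible(x)
}

# default phase refinement threshold: 3 x robust sigma of phase outside all
# coarse masks ("the unwanted background has a low phase shift near zero").
default_tau <- function(phase, masks) {
  phi <- if (inherits(phase, "glim_phase")) phase$phi else phase
  outside <- array(TRUE, dim = dim(phi))
  for (m in masks) outside[m$coarse] <- FALSE
  3 * robust_sigma(phi[outside])
}

#' Refine a coarse mask using the phase tomogram
#'
#' Removes voxels whose absolute phase is at or below `tau` — background in
#' these tomograms sits near zero phase — while *retaining* negative-phase
#' voxels, so that phase-depleted (damaged) cells remain measurable and can
#' produce their diagnostic negative total dry mass. Refinement is idempotent
#' and never adds voxels.
#'
#' @param mask A `glim_mask` (needs `coarse`).
#' @param phase A `glim_phase` on the same grid.
#' @param tau Phase threshold in rad; default
#'   `3 * robust sigma of the phase outside the mask` (compute it once across
#'   all cells with [segment_cells()] for a shared threshold).
#' @return The mask with `refined` filled; empty refinement warns and yields
#'   an all-`FALSE` mask (the cell is excluded downstream with a logged
#'   reason).
#' @export
refine_mask <- function(mask, phase, tau = NULL) {
  stopifnot(inherits(mask, "glim_mask"))
  phi <- if (inherits(phase, "glim_phase")) phase$phi else phase
  if (!identical(dim(phi), dim(mask$coarse))) {
    stop(sprintf("mask grid %s does not match phase grid %s",
                 paste(dim(mask$coarse), collapse = "x"),
                 paste(dim(phi), collapse = "x")), call. = FALSE)
  }
  if (is.null(tau)) tau <- default_tau(phase, list(mask))
  refined <- mask$coarse & (abs(phi) > tau)
  if (!any(refined)) {
    warning(sprintf("cell %s: refinement removed every voxel (all |phase| <= %.4g rad)",
                    mask$cell_id, tau))
  }
  mask$refined <- refined
  mask$tau <- tau
  mask
}

#' Voxelize and refine a set of traces against one tomogram
#'
#' Convenience wrapper: voxelizes every trace, computes a single refinement
#' threshold from the phase outside the union of all coarse masks, and
#' refines each mask with it.
#'
#' @param traces List of [cell_trace()] objects.
#' @param phase A `glim_phase` tomogram.
#' @param tau Optional shared threshold (rad); default 3 x robust background
#'   sigma.
#' @return List of refined `glim_mask` objects.
#' @export
segment_cells <- function(traces, phase, tau = NULL) {
  stopifnot(inherits(phase, "glim_phase"))
  masks <- lapply(traces, voxelize_trace, grid_shape = dim(phase$phi),
                  voxel_um = phase$voxel_um)
  if (is.null(tau)) tau <- default_tau(phase, masks)
  lapply(masks, refine_mask, phase = phase, tau = tau)
}

#' 26-connected component labelling of a 3D mask
#'
#' @param mask Logical (or coercible) 3D array.
#' @return Integer array of the same shape; attribute `n_components`.
#' @export
label_components <- function(mask) {
  stopifnot(length(dim(mask)) == 3)
  .label3d_cpp(array(as.logical(mask), dim = dim(mask)), as.integer(dim(mask)))
}

#' Derive coarse traces from a fluorescence-like channel
#'
#' Thresholds the channel (Otsu by default), labels 26-connected components,
#' and exports each component's per-slice convex outline on every `every_k`-th
#' occupied slice, mimicking coarse manual tracing. Touching cells may merge
#' under the threshold, in which case fewer traces than true cells are
#' returned (a message reports the count).
#'
#' @param channel 3D array (e.g. from [fluorescence_channel()]).
#' @param threshold `"halfmax"` (default: halfway between the median
#'   background level and the 99.9th-percentile foreground level — robust
#'   when labelled cells occupy a small fraction of the volume), `"otsu"`,
#'   `"quantile"`, or `"absolute"`.
#' @param value Quantile (default 0.95) or absolute threshold for those
#'   policies.
#' @param every_k Export outlines on every k-th occupied slice (default 2).
#' @param margin_px Outward dilation of each polygon in pixels (default 2);
#'   a safety margin so the coarse hull encloses the blurred cell boundary,
#'   which phase refinement then trims back.
#' @param min_voxels Discard components smaller than this (default 30).
#' @return List of `glim_trace` objects (possibly empty).
#' @export
traces_from_fluorescence <- function(channel, threshold = c("halfmax", "otsu", "quantile", "absolute"),
                                     value = 0.95, every_k = 2, margin_px = 2,
                                     min_voxels = 30) {
  threshold <- match.arg(threshold)
  stopifnot(length(dim(channel)) == 3)
  thr <- switch(threshold,
    halfmax = {
      bg <- stats::median(channel)
      peak <- stats::quantile(channel, 0.999, names = FALSE)
      bg + 0.5 * (peak - bg)
    },
    otsu = {
      rng <- range(channel)
      if (diff(rng) == 0) Inf else {
        norm <- (channel - rng[1]) / diff(rng)
        EBImage::otsu(norm, range = c(0, 1)) * diff(rng) + rng[1]
      }
    },
    quantile = stats::quantile(channel, value),
    absolute = value
  )
  lab <- label_components(channel > thr)
  n <- attr(lab, "n_components")
  if (n == 0) return(list())
  traces <- traces_from_label_array(lab, every_k = every_k,
                                    margin_px = margin_px,
                                    min_voxels = min_voxels,
                                    source = "fluorescence")
  message(sprintf("traces_from_fluorescence: %d component(s) above threshold %.3g, %d trace(s) exported",
                  n, thr, length(traces)))
  traces
}

#' Coarse traces from an integer label array
#'
#' Shared outline exporter: for every positive label, takes the 2D convex
#' outline of its pixels on every `every_k`-th occupied z-slice, dilated
#' outward by `margin_px`. Used for fluorescence-derived traces and for
#' ground-truth-derived traces in recovery tests.
#'
#' @param lab Integer 3D array (0 background).
#' @inheritParams traces_from_fluorescence
#' @param source Trace source tag.
#' @return List of `glim_trace` objects; components spanning fewer than two
#'   usable slices are skipped with a message.
#' @export
traces_from_label_array <- function(lab, every_k = 2, margin_px = 2,
                                    min_voxels = 1, source = "fluorescence") {
  idx <- which(lab > 0)
  vals <- lab[idx]
  sizes <- tabulate(vals)
  ids <- which(sizes >= min_voxels)
  coords <- arrayInd(idx, dim(lab))
  rows_by_id <- split(seq_along(idx), vals)
  out <- list()
  for (id in ids) {
    w <- coords[rows_by_id[[as.character(id)]], , drop = FALSE]
    zs <- sort(unique(w[, 3]))
    zs <- zs[seq(1, length(zs), by = every_k)]
    polys <- list()
    for (z in zs) {
      pix <- w[w[, 3] == z, , drop = FALSE]
      if (nrow(pix) < 3) next
      xy <- cbind(pix[, 2] - 1, pix[, 1] - 1)  # (x, y), 0-based
      h <- grDevices::chull(xy)
      if (length(h) < 3) next
      v <- xy[h, , drop = FALSE]
      ctr <- colMeans(v)
      dir <- sweep(v, 2, ctr)
      len <- sqrt(rowSums(dir^2))
      len[len == 0] <- 1
      v <- v + margin_px * dir / len
      v[, 1] <- pmin(pmax(v[, 1], 0), dim(lab)[2] - 1)
      v[, 2] <- pmin(pmax(v[, 2], 0), dim(lab)[1] - 1)
      polys[[length(polys) + 1L]] <- list(z = z - 1L, xy = v)
    }
    if (length(unique(vapply(polys, function(p) p$z, numeric(1)))) < 2) {
      message(sprintf("component %s spans fewer than 2 usable z-slices; skipped", id))
      next
    }
    out[[length(out) + 1L]] <- cell_trace(id, polys, source = source)
  }
  out
}
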
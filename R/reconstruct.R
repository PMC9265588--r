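# Phase retrieval from 4-frame stacks and Hilbert-transform integration.

#' Retrieve the phase gradient from a four-frame stack
#'
#' From the four phase-shifted irradiances the sheared phase difference and
#' the mutual intensity follow in closed form: with
#' \eqn{I_n = I + I' + 2\gamma\cos(\Delta\phi + n\pi/2)},
#' \deqn{\Delta\phi = \mathrm{atan2}(I_3 - I_1,\; I_0 - I_2), \qquad
#'       \gamma = \tfrac14\sqrt{(I_0 - I_2)^2 + (I_3 - I_1)^2}.}
#' Both frame differences cancel any incoherent background common to the four
#' frames, which is the mechanism by which the method rejects multiple
#' scattering. Pixels whose fringe modulation \eqn{\gamma} falls below a
#' threshold are flagged (`modulation_ok = FALSE`), their \eqn{\Delta\phi}
#' set to 0, and they are excluded from downstream dry-mass sums.
#'
#' @param stack A `glim_stack` (from [simulate_interferograms()] or
#'   [read_stack()]).
#' @param tau_mod Modulation threshold; default `2 *` the robust noise level
#'   of \eqn{\gamma} estimated in a border region of the field.
#' @param border_frac Fraction of the field width used as the border for the
#'   noise estimate (default 0.05, at least 2 pixels).
#' @return A `glim_gradient`: list with arrays `delta_phi` (rad, in
#'   \eqn{(-\pi, \pi]}), `grad_x` (rad/um), `gamma`, logical `modulation_ok`,
#'   plus `tau_mod` and the config.
#' @export
retrieve_phase_gradient <- function(stack, tau_mod = NULL, border_frac = 0.05) {
  stopifnot(inherits(stack, "glim_stack"))
  f <- stack$frames
  d <- dim(f)
  if (length(d) != 4 || d[4] != 4) {
    stop(sprintf("expected a [y, x, z, 4] frame array, got frame axis %d",
                 if (length(d) == 4) d[4] else NA_integer_), call. = FALSE)
  }
  config <- stack$config
  costerm <- f[, , , 1, drop = FALSE] - f[, , , 3, drop = FALSE]  # 4*gamma*cos
  sinterm <- f[, , , 4, drop = FALSE] - f[, , , 2, drop = FALSE]  # 4*gamma*sin
  dim(costerm) <- d[1:3]; dim(sinterm) <- d[1:3]
  gamma <- sqrt(costerm^2 + sinterm^2) / 4
  dphi <- atan2(sinterm, costerm) * config$grad_sign

  if (is.null(tau_mod)) {
    b <- max(2L, round(border_frac * min(d[1:2])))
    border <- rbind(
      matrix(gamma[c(seq_len(b), d[1] - seq_len(b) + 1L), , ], ncol = 1),
      matrix(gamma[, c(seq_len(b), d[2] - seq_len(b) + 1L), ], ncol = 1)
    )
    tau_mod <- 2 * robust_sigma(border)
    if (!is.finite(tau_mod)) tau_mod <- 0
  }
  ok <- gamma > tau_mod
  if (!any(ok)) {
    warning("no pixel has usable fringe modulation; returning an all-flagged map")
  }
  dphi[!ok] <- 0
  grad <- dphi / config$shear_um
  structure(
    list(delta_phi = dphi, grad_x = grad, gamma = gamma,
         modulation_ok = ok, tau_mod = tau_mod, config = config),
    class = "glim_gradient"
  )
}

#' @export
print.glim_gradient <- function(x, ...) {
  d <- dim(x$delta_phi)
  cat(sprintf(
    "<glim_gradient> %d x %d x %d, %.1f%% modulation-ok, tau_mod = %.3g\n",
    d[1], d[2], d[3], 100 * mean(x$modulation_ok), x$tau_mod))
  invisible(x)
}

#' Integrate a phase gradient to a phase tomogram (Hilbert / spectral)
#'
#' Per focal slice the x-gradient is integrated spectrally:
#' \eqn{\Phi(k_x, k_y) = G(k_x, k_y) / (i k_x)} with a small Tikhonov
#' regularizer \eqn{\eta k_{Nyq}} to keep the division bounded near
#' \eqn{k_x = 0}; the \eqn{k_x = 0} column (per-row mean), which an x-gradient
#' cannot constrain, is set to zero and then re-anchored: by default each row's
#' baseline is taken from the left/right edge columns of the field, which are
#' assumed object-free (`baseline = "edge"`); `baseline = "rowmean"` keeps the
#' zero-row-mean convention instead. Finally the spatial mean of every slice
#' is subtracted — the additive constant of an integrated gradient is not
#' observable.
#'
#' @param gmap A `glim_gradient`, or a matrix/array of x-gradient (rad/um)
#'   with `voxel_um` supplied via `config`.
#' @param eta Regularization as a fraction of the Nyquist frequency
#'   (default 1e-3).
#' @param baseline `"edge"` (default) or `"rowmean"`; see Details.
#' @param edge_cols Number of columns on each side used for the edge baseline
#'   (default 4).
#' @param config Needed only when `gmap` is a bare array.
#' @return A `glim_phase` tomogram (rad), per-slice mean zero.
#' @export
integrate_gradient_hilbert <- function(gmap, eta = 1e-3,
                                       baseline = c("edge", "rowmean"),
                                       edge_cols = 4, config = NULL) {
  baseline <- match.arg(baseline)
  if (inherits(gmap, "glim_gradient")) {
    g <- gmap$grad_x
    config <- gmap$config
  } else {
    g <- gmap
    if (is.null(config)) stop("`config` is required when passing a bare array")
    config <- as_glim_config(config)
  }
  assert_finite_array(g, "grad_x")
  d <- dim(g)
  if (length(d) == 2) { dim(g) <- c(d, 1); d <- dim(g) }
  if (d[2] < 2) stop("cannot integrate along a 1-pixel-wide x dimension", call. = FALSE)
  dx <- config$voxel_um[1]
  kx <- 2 * pi * fft_freq(d[2], dx)           # rad/um
  k_nyq <- pi / dx
  eps <- eta * k_nyq
  # divisor 1/(i*kx), regularized; kx = 0 column removed
  inv <- -1i * kx / (kx^2 + eps^2)
  inv[1] <- 0
  phi <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    G <- fft2(g[, , z])
    P <- sweep(G, 2, inv, `*`)
    p <- Re(ifft2(P))
    if (baseline == "edge") {
      ec <- min(edge_cols, floor(d[2] / 4))
      edges <- cbind(p[, seq_len(ec), drop = FALSE],
                     p[, d[2] - seq_len(ec) + 1L, drop = FALSE])
      p <- p - rowMeans(edges)
    }
    phi[, , z] <- p - mean(p)
  }
  new_phase(phi, config$voxel_um,
            provenance = list(source = "hilbert_integration", eta = eta,
                              baseline = baseline,
                              wavelength = config$wavelength,
                              axial_psf_um = config$axial_psf_um))
}

#' Radially averaged power spectrum of an image
#'
#' Magnitude-squared 2D spectrum, averaged over rings of constant spatial
#' frequency, normalized to unit maximum. Used as the contrast QC comparing
#' the reconstructed phase with a raw DIC-like frame: scattering background
#' buries the high-frequency content of the raw frame, while phase retrieval
#' restores it.
#'
#' @param image 2D matrix (finite values).
#' @param pixel_um Pixel size in um (default 1).
#' @param config Optional [acquisition_config()]; supplies `pixel_um` and the
#'   diffraction-limit reference frequency `2 NA / lambda`.
#' @param nbins Number of radial bins (default half the smaller image side).
#' @return A tibble with `freq` (cycles/um), `power`, `log_power`
#'   (log10, normalized to unit max), and attribute / column
#'   `diffraction_limit` (cycles/um) when a config is given.
#' @export
radial_power_spectrum <- function(image, pixel_um = 1, config = NULL,
                                  nbins = NULL) {
  stopifnot(is.matrix(image))
  assert_finite_array(image, "image")
  if (!is.null(config)) {
    config <- as_glim_config(config)
    pixel_um <- config$voxel_um[1]
  }
  d <- dim(image)
  P <- Mod(fft2(image))^2
  fy <- fft_freq(d[1], pixel_um)
  fx <- fft_freq(d[2], pixel_um)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  if (is.null(nbins)) nbins <- floor(min(d) / 2)
  f_max <- min(max(abs(fy)), max(abs(fx)))
  edges <- seq(0, f_max, length.out = nbins + 1)
  bin <- findInterval(fr, edges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= nbins
  pw <- as.numeric(tapply(P[keep], bin[keep], mean))
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  present <- sort(unique(bin[keep]))
  out <- tibble::tibble(freq = ctr[present], power = pw)
  out$power <- out$power / max(out$power)
  out$log_power <- log10(pmax(out$power, .Machine$double.xmin))
  dl <- if (!is.null(config)) 2 * config$na / config$wavelength else NA_real_
  out$diffraction_limit <- dl
  attr(out, "diffraction_limit") <- dl
  out
}

#' Fraction of off-DC spectral power above a frequency
#'
#' Convenience QC statistic: the share of non-DC power of `image` carried by
#' spatial frequencies above `f_cut` (cycles/um).
#' @inheritParams radial_power_spectrum
#' @param f_cut Cut-off frequency in cycles/um.
#' @export
high_frequency_fraction <- function(image, f_cut, pixel_um = 1, config = NULL) {
  if (!is.null(config)) pixel_um <- as_glim_config(config)$voxel_um[1]
  d <- dim(image)
  P <- Mod(fft2(image - mean(image)))^2
  fy <- fft_freq(d[1], pixel_um)
  fx <- fft_freq(d[2], pixel_um)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  tot <- sum(P[fr > 0])
  if (tot == 0) return(0)
  sum(P[fr > f_cut]) / tot
}
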
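# Internal numeric helpers: unit conversions, FFT utilities, robust scale.

# 1 pg / um^3 == 1000 g/L; alpha in mL/g converts to um^3/pg by the same
# factor chain (1 mL = 1e12 um^3, 1 g = 1e12 pg), i.e. numerically unchanged.
PG_PER_UM3_TO_G_PER_L <- 1000

#' Convert a refractive-index increment from mL/g to um^3/pg
#' @noRd
alpha_um3_per_pg <- function(alpha_ml_per_g) alpha_ml_per_g

# DFT sample frequencies (cycles per unit), matching the layout of stats::fft.
fft_freq <- function(n, d = 1) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1L))
  k / (n * d)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Robust sigma via the median absolute deviation (normal-consistent).
robust_sigma <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  stats::mad(x, constant = 1.4826)
}

# Shift a matrix along its columns (the x axis) by `s` pixels with replicated
# edges; g[, x] = m[, x + s].  Integer shifts are pure indexing; fractional
# shifts use Fourier interpolation on an edge-padded copy to avoid wraparound.
shift_x <- function(m, s) {
  nx <- ncol(m)
  if (nx < 2) stop("shift_x needs at least 2 columns")
  if (abs(s - round(s)) < 1e-9) {
    s <- as.integer(round(s))
    idx <- pmin(pmax(seq_len(nx) + s, 1L), nx)
    return(m[, idx, drop = FALSE])
  }
  pad <- as.integer(ceiling(abs(s)) + 2L)
  mp <- cbind(
    m[, rep(1L, pad), drop = FALSE], m,
    m[, rep(nx, pad), drop = FALSE]
  )
  np <- ncol(mp)
  k <- fft_freq(np)
  ph <- exp(2i * pi * k * s)
  # FFT along rows (x): transpose so columns are x, use mvfft
  g <- t(Re(stats::mvfft(stats::mvfft(t(mp)) * ph, inverse = TRUE) / np))
  g[, pad + seq_len(nx), drop = FALSE]
}

# Separable Gaussian blur of a 3D array via FFT, periodic boundaries.
# sigma is a length-3 vector in voxels; sigma = 0 skips that axis.
gauss_blur3 <- function(a, sigma) {
  d <- dim(a)
  stopifnot(length(d) == 3, length(sigma) == 3)
  ft <- stats::fft(a)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    f <- fft_freq(d[ax])
    g <- exp(-2 * pi^2 * sigma[ax]^2 * f^2)
    shape <- c(1, 1, 1); shape[ax] <- d[ax]
    ft <- ft * array(rep(g, each = prod(d[seq_len(ax - 1)])), dim = d)
  }
  Re(stats::fft(ft, inverse = TRUE) / length(a))
}

# Deterministic child seed derived from a base seed and a stream index,
# kept below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 111 * as.numeric(stream)) %% 2147483629 + 1
}

assert_finite_array <- function(x, name) {
  if (!all(is.finite(x))) stop(sprintf("`%s` must be finite everywhere", name), call. = FALSE)
  invisible(x)
}
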
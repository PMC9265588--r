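# Shared fixtures and independent oracles, built in code at test time.

# quantize to IEEE float32, the storage precision of the TIFF writers
f32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4),
                           "numeric", n = length(x), size = 4)

# small test configs
cfg_px <- function(...) acquisition_config(voxel_um = c(1, 1, 1), shear_um = 1, ...)
cfg_small <- function(seed = 1L) {
  acquisition_config(voxel_um = c(0.5, 0.5, 1), shear_um = 0.5, seed = seed)
}

# brute-force two-sided exact Mann-Whitney p by enumerating every assignment
# of n1 of the pooled values to the first sample (midranks; two-sided = twice
# the smaller tail of the rank-sum distribution, capped at 1)
mw_brute_force <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  r1_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  sums <- apply(combos, 2, function(i) sum(r[i]))
  lo <- mean(sums <= r1_obs + 1e-9)
  hi <- mean(sums >= r1_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# closed-form membership oracles for simple solids (voxel centers at integer
# coordinates, physical units = voxel units)
in_cube_oracle <- function(p, lo = 0, hi = 9) {
  all(p >= lo - 1e-9) && all(p <= hi + 1e-9)
}
in_tetra_oracle <- function(p, s = 10) {
  all(p >= -1e-9) && (sum(p) <= s + 1e-9)
}

# brute-force axial projection: direct convolution of a contrast column with
# the triangular sectioning weights
project_column_oracle <- function(dn_col, wavelength, axial_psf, dz) {
  half <- axial_psf / 2
  ks <- seq(-floor(half / dz), floor(half / dz))
  t <- pmax(0, 1 - abs(ks * dz) / half)
  if (sum(t) == 0) { ks <- 0L; t <- 1 }
  w <- t / sum(t) * axial_psf
  nz <- length(dn_col)
  phi <- numeric(nz)
  for (z in seq_len(nz)) {
    for (j in seq_along(ks)) {
      src <- z + ks[j]
      if (src >= 1 && src <= nz) phi[z] <- phi[z] + w[j] * dn_col[src]
    }
  }
  phi * 2 * pi / wavelength
}

# per-animal centering: forces the estimated animal variance component to the
# boundary (zero) so the mixed model provably coincides with plain ANOVA
center_animals <- function(records, col = "volume_um3") {
  for (a in unique(records$animal_id)) {
    i <- records$animal_id == a
    g <- records$group[i][1]
    gm <- mean(records[[col]][records$group == g])
    records[[col]][i] <- records[[col]][i] - mean(records[[col]][i]) + gm
  }
  records
}

# records lying exactly on volume = slope * mass (slope in L/g)
records_on_line <- function(slope_L_per_g, mass_pg = c(10, 20, 30, 40, 50),
                            group = "day") {
  tibble::tibble(
    cell_id = seq_along(mass_pg), animal_id = "a1", group = group,
    drymass_pg = mass_pg,
    volume_um3 = mass_pg * slope_L_per_g * 1e3,  # pg * L/g -> um^3
    damaged = FALSE
  )
}

# match each recovered mask to the ground-truth label it overlaps most
match_mask_to_truth <- function(mask, labels) {
  tl <- labels[mask$refined]
  tl <- tl[tl > 0]
  if (!length(tl)) return(NA_integer_)
  as.integer(names(which.max(table(tl))))
}
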
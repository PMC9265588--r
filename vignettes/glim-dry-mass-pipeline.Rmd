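---
title: "From sheared interferograms to single-cell dry mass: the glimquant methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sheared interferograms to single-cell dry mass: the glimquant methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glimquant)
```

## The measurement problem

Gradient light interference microscopy (GLIM) augments a DIC microscope with a
variable retarder that steps the phase offset between the two sheared,
orthogonally polarized beams through $\epsilon_n = n\pi/2$, $n = 0,1,2,3$.
The irradiance at the detector for each step is

$$I_n(\mathbf r) = I + I' + 2\gamma(\mathbf r)\,
  \cos\!\big(\Delta\phi(\mathbf r) + \epsilon_n\big),$$

where $\Delta\phi(\mathbf r) = \phi(\mathbf r + \delta_x \hat x) -
\phi(\mathbf r)$ is the specimen phase difference across the shear
$\delta_x$ and $\gamma$ is the mutual intensity (fringe modulation) of the
two fields. Because an incoherent multiple-scattering background adds the
same offset to all four frames, it cancels in the two frame differences used
by the retrieval — this is what makes the method usable hundreds of microns
deep in strongly scattering tissue, and it is verified exactly in the test
suite.

From the four frames the package computes, per pixel,

$$\Delta\phi = \operatorname{atan2}(I_3 - I_1,\; I_0 - I_2), \qquad
  \gamma = \tfrac14\sqrt{(I_0-I_2)^2 + (I_3-I_1)^2},$$

and the lateral phase gradient $\nabla_x \phi \simeq \Delta\phi/\delta_x$.
A sign switch (`grad_sign`) accommodates datasets with reversed shear
orientation. Pixels whose modulation falls below a threshold
$\tau_{mod}$ (default twice the robust noise level of $\gamma$ in a border
region) are flagged and excluded from densitometry rather than inverted.

## Hilbert (spectral) integration and its one unavoidable convention

The gradient is integrated per focal slice in the Fourier domain:
$\Phi(k_x,k_y) = G(k_x,k_y)\,(-i k_x)/(k_x^2 + \eta^2)$ with
$\eta = 10^{-3} k_{\mathrm{Nyq}}$, a Tikhonov-regularized division by
$i k_x$ that avoids blow-up near $k_x = 0$. Any such integrator leaves two
gauges free:

* the global additive constant — never observable; every slice is normalized
  to zero spatial mean;
* the $k_x = 0$ column, i.e. each row's mean — an $x$-gradient contains *no*
  information about it.

For the second gauge the package re-anchors each row's baseline to the
left/right edge columns of the field (`baseline = "edge"`, default), which
is correct whenever the field margins are object-free — true for the
bundled simulations, and the usual situation for a soma-centred field of
view. `baseline = "rowmean"` keeps the zero-row-mean convention instead.
Without edge anchoring, a localized object's row means are irrecoverable in
principle and a Gaussian-bump recovery saturates at a few percent RMSE; with
it the bump is recovered to better than 0.1% of its amplitude.

## The forward simulator and what it does (not) emulate

No instrument data accompany the method, so every stage is validated against
a forward model with exact ground truth. `make_phantom()` places
non-overlapping, slightly anisotropic ellipsoidal "somata" (default peak
contrast $\delta n = 0.02$ over $n_0 = 1.337$) in a correlated Gaussian
random field standing in for residual tissue texture (default contrast sd
0.001, correlation length 1.5 µm — phase sd ≈ 12 mrad against a soma peak of
≈ 242 mrad). The contrast profile is flat with a cosine roll-off over the
outer 5% of the radius: the model applies no lateral PSF, so a membrane-bound
boundary is optically sharp and the roll-off only provides sub-voxel
anti-aliasing. Ground truth is exact by construction: volume is the labelled
voxel count times the voxel volume, mass the contrast integral over the
label divided by $\alpha$.

Optical sectioning is a normalized triangular axial kernel of full width
1.5 µm (the instrument's axial resolution): slice $z$ reports the phase of an
effective slab of that thickness, so a column of constant $\delta n$ thicker
than the kernel gives $\phi = (2\pi/\lambda)\,\delta n\, \zeta$ with
$\zeta = 1.5$ µm. The kernel shape is configurable; only its width and unit
normalization matter for mass conservation. `simulate_interferograms()` then
renders the four frames with optional Gaussian read noise and an optional
incoherent background grid.

The simulator deliberately omits: lateral diffraction blur, multiple
scattering beyond an additive incoherent offset and a static phase texture,
camera-specific noise, and fluorophore photophysics (the SR101-like channel
is simply the blurred cell support with Poisson noise). Passing tests
therefore demonstrate correctness of the *computation* under a faithful
four-frame interference model — not robustness to every optical artifact of
a real microscope.

## Segmentation: sparse traces, convex hulls, phase refinement

Cells are annotated by a handful of per-slice polygons (manual ImageJ-style
traces or contours derived from the fluorescence channel every second
occupied slice, dilated by a 2-pixel safety margin). The polygon vertices,
lifted to physical coordinates with the true voxel anisotropy, are
triangulated and a voxel joins the coarse mask iff its center lies inside
the resulting mesh — for a raw point cloud the union of Delaunay tetrahedra
is the convex hull, so membership is evaluated as half-space tests against
the quickhull facets, with boundary ties broken toward inclusion.
Concavities cannot be represented; the procedure targets cell bodies, not
arborizations.

The coarse hull is then refined by the phase signal itself: voxels with
$|\phi| \le \tau$ are removed, with $\tau$ defaulting to three times the
robust sigma of the phase outside all coarse masks. Two consequences are
intentional:

* voxels with *negative* phase are retained, so a phase-depleted (damaged)
  cell keeps its voxels and can exhibit the diagnostic negative total dry
  mass — resolving in favour of measurability the tension between
  "accumulate positive phase" and the reported negative-mass cells;
* refinement never adds voxels and is idempotent.

The fluorescence channel is thresholded halfway between the median
(background) level and the 99.9th percentile (cell interior) by default;
Otsu, quantile and absolute policies are available. Touching somata may
merge into one trace — the count can only fall below the truth, and merges
are logged.

## Densitometry

Dry mass follows from the scattering-potential integral
$m = \chi$-integral$/(2 n_0 \alpha)$, which for small contrast reduces to
$m = \alpha^{-1} \int \delta n \, dV$ with $\alpha = 0.2$ mL/g, the standard
refractive-index increment of cellular dry matter. For a z-stack the naive
"sum the phase over the 3D mask" over-counts: each physical voxel
contributes to every slice within the axial kernel support. The package
therefore inverts the sectioning model per voxel,
$\delta n = \phi \lambda /(2\pi\zeta)$, before summing — with $\zeta$ the
same axial width used in projection, mass is conserved exactly for any cell
thicker than the kernel (verified by the 5-µm-sphere oracle: closed form
52.36 pg, pipeline within 5%). An alternative `slice2d` mode implements
classic 2D QPI densitometry on the best-focus slice. Since the integrated
tomogram is normalized to zero mean per slice, the cell table re-anchors the
zero level to the per-slice median phase outside all coarse masks before
summing; masses are otherwise biased low by a few percent in proportion to
the cell fill fraction of the field.

Units are fixed throughout: phase rad, lengths µm, mass pg, density g/L
(1 pg/µm³ = 1000 g/L); `volume = n_voxels x dx dy dz` exactly, and
`damaged = (dry mass < 0)`.

## Group statistics

Two tests are always reported, mirroring the two analyses used for
day/night comparisons of this kind:

* **Mann-Whitney**, with midrank ties. The exact two-sided p (twice the
  smaller tail of the rank-sum distribution) is computed by dynamic
  programming over the observed midranks whenever $n_1 n_2 \le 400$ —
  equivalent to enumerating all arrangements, and checked against literal
  `combn` enumeration for small samples. Above the limit a tie-corrected,
  continuity-corrected normal approximation is used.
* **One-way mixed-model ANOVA**: `value ~ group + (1 | animal)` by REML with
  Satterthwaite denominator degrees of freedom, because cells are nested in
  animals and pooling them would overstate the evidence. With two groups the
  Tukey post-hoc contrast coincides with the group test; it is reported for
  completeness. When the estimated animal variance is zero the F statistic
  provably equals the plain one-way ANOVA F, which the tests assert to
  1e-6.

The `significant` flag in `compare_groups()` follows the mixed model by
default (configurable), at the conventional 0.05 level; SEM is computed over
cells, matching the way such cohorts are usually displayed, with an optional
animal-level aggregation. The volume-vs-mass relation is summarized by OLS
of volume (L) on mass (g); the reciprocal slope is the group's density in
g/L, displayed at two significant figures — the printed slopes
$1.02\times10^{-3}$ and $1.17\times10^{-3}$ L/g imply 980 and 850 g/L.

## The synthetic cohort

`simulate_cohort()` renders one tomogram per animal (9 animals and 7 cells
per animal per group by default — the design scale of the motivating study)
and pushes every cell through the complete chain: phantom, interferograms,
retrieval, integration, fluorescence-derived traces, voxelization,
refinement, densitometry. Night cells are generated at 75% of the day volume
at constant expected dry mass (contrast scales reciprocally), emulating
osmotic volume regulation. Biological variability is log-normal and chosen
once as a realistic regime: cell-level sd 0.20 and animal-level sd 0.08 for
both volume and mass; volume and mass factors are drawn independently —
allometry between cell size and mass is deliberately not modelled, since the
estimand is the group contrast, not the within-group slope. Tomograms are
120 × 120 × 27 voxels at (0.375, 0.375, 1.0) µm — a 45 × 45 × 27 µm field,
the same depth and sampling regime as the motivating acquisitions at reduced
lateral extent, which keeps a 50-replicate cohort study tractable on one
CPU. The record-level twin `simulate_cohort_records()` draws measurement
outcomes directly from the same biological model and is used where
thousands of model fits are needed (type-I and power calibration).

## Numerical choices and degenerate inputs

* Shear is expressed in µm and converted to pixels; integer shifts are pure
  indexing, fractional shifts use Fourier interpolation on an edge-padded
  copy. Shears below one pixel are refused with advice to supersample.
* No phase unwrapping: per-slice gradients are assumed within $(-\pi,\pi]$,
  valid for thin-specimen sectioned phase; steep objects are a documented
  limitation.
* Quickhull uses a tolerance of $10^{-9}$ of the cloud extent; coplanar or
  collinear traces raise degenerate-volume errors, as does a single-slice
  trace.
* An all-zero stack retrieves an all-flagged map with a warning rather than
  an error; empty refined masks are dropped from the cell table with a
  logged reason.
* Every simulation consumes an explicit seed; fixed seeds give bit-identical
  phantoms, stacks, and pipeline outputs.

## Known limitations

Convex hulls cannot follow concave somata or processes; volume is reported
from the refined mask (the coarse count is kept alongside); the mass scale
inherits any bias in $\alpha$ and in the dense-background assumption of the
zero-level anchoring; and the simulator's omissions listed above mean that
agreement with real instrument data must be established separately.
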
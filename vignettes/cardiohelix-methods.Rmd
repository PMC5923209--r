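---
title: "Methods: dual-modality helix-angle transmurality mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality helix-angle transmurality mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, conventions,
parameter choices and known limitations. Every empirical statement made
here is one the test suite or `scripts/acceptance.R` computes; nothing
is quoted from measurements the package cannot rerun.

## Coordinate conventions

Voxel indices are 1-based inside R and documented as 0-based in all
written files; the centre of voxel *(i, j, k)* lies at
*(i − 1/2)·s* in physical micrometres for spacing *s*. The long axis is
always the third array axis, slices ordered base to apex, so short-axis
planes are *xy* planes. The per-slice cardiac frame is built from the
blood-pool centroid: radial r̂ points in-plane from the centre to the
voxel, longitudinal ℓ̂ is +z, circumferential ĉ = ℓ̂ × r̂. Angles are
degrees externally and radians internally.

**Helix angle.** The fiber (axial, sign-free) direction is projected
onto the ĉ–ℓ̂ tangent plane; HA is the signed angle of that projection
from ĉ toward ℓ̂, canonicalized to (−90°, 90°] by making the ĉ-component
non-negative (a purely longitudinal projection is +90°). Positive HA is
a right-handed helix, so a normal wall runs from positive HA at the
endocardium to negative at the epicardium and the signed HA-vs-TD slope
is negative; outputs report both the signed slope and its magnitude.
Streeter-style definitions admit variants (projection versus direct
angle); the projection form above is this package's convention and is
not claimed to be byte-identical to any other implementation. Fibers
whose tangent-plane projection norm falls below 0.1 are flagged
undefined rather than given a meaningless angle.

**Transmural depth.** TD is measured along in-plane radial rays (not 3D
wall normals), because every quantity here is defined per short-axis
plane. Wall crossings are located by scanning the rasterised mask along
each ray at quarter-voxel steps and placing the boundary at the
transition midpoint; each myocardial voxel inherits the boundaries of
its azimuthal bin (360 bins/slice by default). Rays whose wall run
contains gaps — infarct thinning, segmentation holes — are flagged and
excluded rather than interpolated across.

## DTI path

The tensor is estimated by the ordinary (unweighted) log-linear
least-squares fit of ln S = ln S0 − b gᵀDg over the seven unknowns (six
components + ln S0); the b-matrix is b·ggᵀ exactly, with no imaging
cross-term correction. Weighted least squares is deliberately not used.
Non-positive signals are clamped to 1e−6 of the maximum b = 0 signal
before the log (avoiding −∞ without biasing typical voxels); a voxel
with at least half its signals non-positive is masked out, and no
negative-eigenvalue repair is attempted beyond flagging — flagged and
degenerate (isotropic within 1e−6 relative spread) voxels are excluded
from all HA statistics. A rank check on the design matrix rejects
direction sets that do not span the six components.

The default protocol is one b = 0 volume plus twelve b = 1000 s/mm²
directions from a deterministic electrostatic-repulsion set (Fibonacci
hemisphere initialisation, antipodally symmetric Coulomb descent). The
direction scheme and S0 are configurable because no canonical printed
set exists for this design; the chosen set is written into every
protocol file the package emits.

Myocardium segmentation on the DTI path thresholds the mean
diffusion-weighted attenuation (default 0.25 of the b = 0 level): the
blood pool, being nearly free water, attenuates far more strongly than
tissue, so a single threshold separates wall from pool and background;
the largest connected component is kept and the enclosed per-slice
cavity becomes the blood pool.

Mean diffusivity is trace/3 in µm²/ms, and the infarct zoning uses the
fixed thresholds: infarct MD > 1.12 µm²/ms, peri-infarct 0.9–1.12,
remote ≤ 0.9. The non-infarct threshold is read as 0.9 µm²/ms so the
three zones partition the wall, and this is recorded in output
metadata. Infarct voxels and infarct-crossing profiles are excluded
from every HAT statistic.

## Optical path

Stripe (shadow) artifacts of light-sheet illumination run along the
illumination axis, concentrating spectral energy in a narrow band of
near-zero frequency along that axis. The filter damps that band with a
Gaussian notch per slice while *protecting* low perpendicular
frequencies (default Gaussian width 4 bins), so large-scale anatomy —
which also lives at near-zero stripe-axis frequency — is not removed
with the stripes. Strength 0 is a bit-exact no-op. An inherent
trade-off remains: genuine texture whose variation is exactly
perpendicular to the illumination axis overlaps the notch and is
partially attenuated; this is true of any Fourier destriping method.

Gradients come from the separable smoothed-derivative Sobel triple,
normalised so a unit intensity ramp yields a unit gradient, with
reflective boundaries and a flagged one-voxel boundary layer. Gradient
components are divided by the physical voxel size per axis *before*
tensor formation, otherwise anisotropic voxels bias through-plane
angles. The structure tensor is the Gaussian-windowed average of the
gradient outer products; orientation is the smallest-eigenvalue
eigenvector (second of two in 2D, third of three in 3D), coherence is
(λmax − λmin)/(λmax + λmin) with 0 for a vanishing tensor, and voxels
below the coherence threshold (default 0.1) are flagged undefined and
excluded downstream.

The window width is a genuine free parameter (no canonical value
exists): the exported default is 4 voxels, appropriate when the stripe
wavelength is well resolved; the phantom study uses 3 voxels because
its texture wavelength is 6 optical voxels and a window much wider than
the wavelength needlessly blurs the transmural HA ramp. The window is
always recorded in output metadata.

For cross-modality comparison the optical HA map is computed at optical
resolution and then block-averaged to the DTI grid (exact
partial-volume weights, NA-aware; masks by majority vote). Averaging HA
values directly is safe here because phantom helix angles stay well
inside (−90°, 90°) so no axial wrap-around occurs across a block.

Mask segmentation on the optical path thresholds a Gaussian-smoothed
copy of the intensity (default σ = 3 voxels): the fibrous texture
itself would otherwise punch salt-holes through the mask and invalidate
transmural rays.

## Transmurality quantification

Per slice, 20 equally spaced rays (reference azimuth 0 = +x; real-data
use should supply the RV-insertion anchor) sample HA by nearest voxel
at 8 equally spaced TD stations — mid-block positions
TD = (k − 1/2)/8·100. A profile needs ≥ 4 valid stations and ≥ 10 %TD
spread or it is dropped and counted. Global HAT is the unweighted mean
of per-profile OLS slopes; per-slice means are kept as intermediates.
Regional variants: the AHA 16-segment model (basal/mid/apical thirds of
the analysed slices, 6/6/4 azimuthal sectors; a segment containing any
infarct-crossing profile is omitted, never zero-filled) and 100 radial
segments of 3.6° pooled across slices. With 20 rays per slice, 20 of
the 100 radial bins are populated; the bins exist so that analyses with
denser ray sets drop in unchanged. Whether the 20 projections should be
pooled per heart or kept per slice is ambiguous in the field; per-slice
is adopted because all slices are analysed.

## Tractography

FACT keeps the orientation constant within each voxel, steps
bidirectionally from every seed (default step = half the smallest voxel
dimension; default 10³ sub-voxel seeds per voxel, configurable), flips
the eigenvector sign per step for antipodal continuity, and terminates
on mask exit, turning angle above 60°, or 5000 steps — step, threshold
and cap are this package's defaults, stated here because no canonical
values exist. Tracking is deterministic. Tractography is used for
sub-voxel visualisation and a consistency check (per-streamline mean
|HA| versus the voxelwise map); no quantitative tract metric is defined.

## Agreement statistics

Bland-Altman uses differences x − y (order printed in every output),
bias = mean difference, limits of agreement = bias ± 1.96·sd (sample,
n − 1). ICC is the two-way single-measure coefficient from the ANOVA
mean squares; because the naming conventions are endlessly confused,
both the absolute-agreement form ICC(A,1) — the headline value — and
the consistency form ICC(C,1) are always reported. Spearman's rho uses
midranks for ties with asymptotic two-sided p-values; R² is from the
OLS line. Group comparisons: Wilcoxon rank-sum for independent groups,
signed-rank or paired t for paired designs; α = 0.05, two-sided.
Mask registration for voxelwise comparison is mutual-information-driven
affine (rigid + optional isotropic scale), initialised from centroids;
a fully non-rigid deformable step is out of scope because phantoms
share geometry, and the transform interface accepts externally supplied
deformations. Dice < 0.5 after registration raises a hard warning.
Outputs label mean, SD and SE explicitly rather than adopting any
ambient ± convention.

## The phantom generator

The generator *is* the study design; its defaults are fixed once:

* Geometry: 64×64×16 grid at 125 µm isotropic, annulus radii
  900/2500 µm. The in-plane resolution matches small-animal DTI; the
  slice direction is made isotropic (rather than 300 µm) so the optical
  rendering can use one refinement factor per axis, and the phantom is
  a mid-ventricular stack rather than a whole heart — apex and valve
  plane are out of scope.
* Fiber field: HA ramps linearly in TD between ±ha (drawn per phantom);
  the true global HAT is (ha_epi − ha_endo)/100 exactly.
* Groups: control-like phantoms draw |HAT| from N(1.31, 0.20) °/%TD and
  ischemic-like from N(0.79, 0.13) — the generative design values —
  with 7 and 8 phantoms per study, and Rician noise σ/S0 = 0.02.
* Diffusion: eigenvalues (1.3, 0.7, 0.5) µm²/ms (MD 0.83, below the
  remote-zone threshold, plausible for fixed tissue), λ1 along the
  fiber, λ3 radial; blood pool isotropic 2.0 µm²/ms; signal
  S = S0·exp(−b gᵀDg); Rician noise via two Gaussian channels, so the
  b = 0 background mean is σ·√(π/2) (checked by a property test).
* Lesion: a transmural angular sector (±30°) with all eigenvalues
  scaled ×1.5 (core MD 1.25 > 1.12) and HA multiplied by 0.4, plus a
  ±14° peri-infarct ring at ×1.25 (MD 1.04 ∈ (0.9, 1.12)) with the
  midpoint HA flattening — so the generative labels land on the correct
  side of both zoning thresholds by construction, and peri-infarct |HAT|
  sits between core and remote.
* Optical texture: the natural "plane-wave stripes perpendicular to the
  fiber" formulation is ill-posed on a curved helical field — the phase
  term x·n̂(x) has a gradient dominated by the spatial rotation of n̂,
  so rendered stripe normals would not be perpendicular to the fiber.
  Instead the texture is rendered by line-integral convolution: seeded
  white noise, pre-smoothed to the stripe wavelength (default 250 µm at
  the 3× refined grid, i.e. 6 optical voxels), is smeared along the
  local fiber direction with a Hann-tapered kernel (default half-length
  2 wavelengths), guaranteeing intensity gradients perpendicular to the
  fiber everywhere. A radial cosine lamination (15% contrast) emulates
  sheet-like layering, optional global shadow stripes emulate
  light-sheet artifacts, and Gaussian noise is added last. Intensities
  are clamped to [0, 1].

The generator is deliberately idealised: it contains no papillary
muscles, no right ventricle (beyond a second centre used only for the
in-plane-angle frame), no histology-scale structures (nuclei, vessels),
no wall thinning, no registration mismatch between modalities, and its
texture wavelength is scaled to the rendered grid rather than to true
laminar dimensions. Passing tests therefore demonstrate that the
*pipeline* is correct and self-consistent under realistic noise — not
that real hearts would yield these numbers. In particular the
cross-modality R² on phantoms is higher than any real-data analogue
because between-phantom design variance dominates measurement error.

## Numerical choices

* Eigendecompositions of the 3×3 symmetric tensors are batched in
  compiled code; eigenvalues are returned descending and e1 is
  canonicalized to the hemisphere of the local ĉ (falling back to +x),
  which only fixes the sign of an axial quantity.
* Separable convolutions (Sobel, Gaussian windows) use shift-and-add
  with reflective boundaries.
* Problem sizes: the study phantoms are 64×64×16 with a 3× refined
  optical grid (192×192×48) — large enough that the annulus spans ~13
  DTI voxels transmurally, small enough that the full 15-phantom study
  and both analysis paths run in minutes on one CPU; the noise-free
  recovery checks use a 64³ stack.
* Determinism: every stochastic step derives from an integer seed via a
  scoped RNG (the caller's RNG state is restored), so any stage rerun
  with the same configuration and seed is bit-identical.
* The destriping notch is evaluated per slice with exact FFTs; only
  coefficients inside the notch change, so out-of-notch energy is
  preserved exactly.

## Known limitations

* TD uses in-plane rays; strongly tilted or apical geometry would need
  3D wall normals, which are out of scope.
* The optical-path HAT on ramped helical fields carries a small
  systematic magnitude inflation (a few percent of the slope) from
  structure-tensor window averaging near the wall boundaries; it is
  well inside the validation tolerances and shared by any windowed
  orientation estimator.
* The AHA segmentation is anchored at the grid +x axis; anatomical
  anchoring (RV insertion) must be supplied for real data.
* Registration is affine-only; deformable alignment must come from
  outside through the transform interface.
* Sheetlet (secondary/tertiary eigenvector) analysis is deliberately
  not implemented.
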
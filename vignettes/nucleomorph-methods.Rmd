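---
title: "nucleomorph: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nucleomorph: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical choices and validation
strategy behind `nucleomorph`: a pipeline for 3D nuclear segmentation and
morphometry of Hoechst-stained confocal stacks, radial chromatin-marker
profiling, FRC resolution estimation of super-resolution micrographs, and
the accompanying expression statistics. It is written for readers who want
to know *why* the defaults are what they are and what a passing test does
and does not establish.

## Image model and conventions

All stacks are scalar intensity arrays in `(z, y, x)` order with a physical
voxel size per axis in nanometres. The default spacing, 150 nm axially and
120 nm laterally, matches the confocal acquisition geometry the pipeline
was designed around (60×/1.49 NA oil objective, 512×512 frames); STED
micrographs for FRC use 35 nm pixels. Intensities are normalized to
`[0, 1]` by the bit-depth maximum wherever absolute values enter a measure
(chromatin density, G1 gating), so results are comparable across 8-bit,
16-bit and float acquisitions. All smoothing scales are stated in x/y-voxel
units and divided per axis by the spacing ratio, so the physical smoothing
is isotropic on the anisotropic grid.

## Segmentation

Segmentation is a two-step procedure: voxel classification to separate
nuclei from background, then shape-based splitting of touching nuclei.

**Feature bank.** For each scale σ the pipeline computes nine per-voxel
features — Gaussian-smoothed intensity, gradient magnitude, the
largest-magnitude Hessian eigenvalue, Laplacian of Gaussian, the largest
structure-tensor eigenvalue, an edge-strength map, difference of Gaussians
(σ vs 1.6σ), and the local mean and variance in a cubic window of side
2σ+1 — plus the raw intensity once. Default scales are {1, 2, 4, 8}
x/y-voxels, spanning texture-to-nucleus length scales at 120 nm pixels.
Two interpretation choices deserve note: "derivatives" are exposed as the
rotation-invariant gradient magnitude rather than per-axis partials
(classifier stability under orientation), and "Canny edges", a 2D notion,
is rendered in 3D as gradient magnitude with non-maximum suppression along
the local gradient direction — the closest 3D analogue of Canny's thinning
step, without its hysteresis stage. The structure tensor contributes its
leading eigenvalue rather than the full tensor.

**Classifier.** A random forest of 200 trees (CART, Gini impurity,
bootstrap resampling, `floor(sqrt(p))` features per split, leaf size ≥ 5,
depth ≤ 25) predicts the probability that a voxel belongs to a nucleus.
No random-forest package exists in the dependency footprint the package
targets, so the ensemble is implemented in compiled code; training uses R's
RNG and is exactly reproducible under a seed. Annotations may be sparse
(interactive-style scribbles as label images) or dense; annotated voxels
are subsampled to at most `max_samples` rows (default 5000) before
training, which on the package's phantoms leaves held-out voxel accuracy
above 0.99 (this is asserted by the acceptance tests, not assumed).

**Mask.** The probability map is thresholded at `p_threshold` (default 0.5,
the neutral choice; exposed in the configuration) and interior cavities are
filled in 3D, since the chromatin channel is often dimmer in nucleoli.
Components smaller than `min_size` voxels (default 500, about 1 µm³ at the
default spacing) are dropped as debris; set 0 to keep everything.

**Splitting.** Touching nuclei are split by marker-controlled watershed.
Seeds are local maxima (26-neighborhood, plateau-inclusive) of the
Euclidean distance transform of the mask, computed in isotropic voxel
units, with height above `seed_threshold` (default 2 voxels — shallow
boundary bumps never seed). The distance transform, not raw intensity, is
used because the splitting criterion is shape: distance maxima mark the
cores of convex bodies regardless of staining texture. Any two seeds at
Euclidean distance `< min_separation` voxels (default 10) are merged by
single-linkage into one marker, implementing the rule that nuclei closer
than 10 voxels are not separated; the rule is read strictly, so a
separation of exactly 10 may split. Distances are seed-to-seed, in voxels,
both stated interpretation choices. The watershed floods the inverted
distance transform from the markers with a FIFO-tie-break priority queue,
so every mask voxel receives a label (the partition property is tested).
Mask components whose distance peak never reaches `seed_threshold` keep a
label of their own rather than disappearing.

The merge boundary is validated with touching-pair phantoms whose distance
maxima sit exactly *s* voxels apart: across *s* = 2…20 the number of labels
is monotone and flips from 1 to 2 exactly at 10.

## Morphometry

- **Volume** is voxel count × voxel volume, reported in µm³.
- **Surface area** is the area of the 0.5-level iso-surface of the lightly
  Gaussian-smoothed binary label, triangulated by marching tetrahedra in
  physical coordinates. Raw voxel-face counting overestimates smooth
  surfaces by up to ~50%, which would corrupt compactness. Smoothing places
  the 0.5 level exactly on a flat binary interface, but biases sharp edges
  inward proportionally to σ; the default therefore measures at σ = 1.2 and
  1.8 x/y-voxels and extrapolates linearly to σ = 0. On the package's
  oracles (voxelized sphere r = 3 µm, ellipsoid 6×4×2 µm, axis-aligned box)
  this keeps errors within the 3% band asserted by the tests.
- **Compactness** is reported both as the raw ratio `C = V²/S³` and as
  `C_norm = 36π·V²/S³`, which is 1 for a sphere and < 1 otherwise. The raw
  ratio is the form the pipeline standardizes on; note that for
  near-spheroidal nuclei its scale is ~0.009, so published compactness
  values on the order of 0.2 imply some additional normalization that is
  not recoverable without the original raw data — both columns are emitted
  so either convention can be compared.
- **Ellipsoid fit**: the second central moments of the voxel coordinate
  cloud (physical units, plus the `spacing²/12` voxel self-variance) are
  eigen-decomposed and converted through the solid-ellipsoid relation
  `rᵢ = √(5λᵢ)`. **Elongation** is `r1/r2`, the ratio of the two main
  radii; whether the "second radius" of a published fit is the intermediate
  or the smallest axis is ambiguous in general, so `elongation_mode =
  "smallest"` switches to `r1/r3`.
- **Chromatin density** is total bit-depth-normalized intensity over the
  label divided by the volume, expressed per voxel volume so that a uniform
  unit-intensity nucleus has density exactly 1 (equivalently: the mean
  normalized intensity). This makes the number dimensionless and
  comparable across acquisitions; an absolute published density scale
  cannot be reproduced without the original images, so only ratios and
  contrasts are meaningful. The stated uniform-field contract (intensity
  0.5 → density 0.5) is the normalization's defining case.
- **G1 gating** is a threshold on the mean normalized CDT1-marker intensity
  over the label (default 0.2), with `≥` at the boundary.

## Radial chromatin profiles

To quantify peripheral vs central marker localization (heterochromatin is
expected at the nuclear envelope, euchromatin toward the center), each
nucleus voxel gets a depth: the Euclidean distance transform in physical
units, normalized by the per-nucleus maximum to d ∈ (0, 1] with 0 at the
envelope. Normalizing per nucleus makes differently sized nuclei
comparable, which is the right trade-off when only relative statements
("closer to the envelope") are of interest. The profile is the mean marker
intensity in equal-width bins of d, and the peripheral enrichment index
(PEI) is the intensity ratio of the shell d < 0.2 to the rest. PEI is the
package's own operationalization of the qualitative observation it serves;
it is labeled as such in outputs, is invariant to global intensity
scaling, and is > 1 for envelope-proximal enrichment.

## FRC resolution

Two equally shaped images of the same field are mean-subtracted, Hann
apodized (suppressing edge artifacts that otherwise inflate high-frequency
correlation), Fourier transformed, and correlated per frequency ring:
`FRC(r) = Re Σ F_A F_B* / √(Σ|F_A|² Σ|F_B|²)`. Resolution is the inverse of
the first frequency at which the curve falls below the threshold, located
by linear interpolation between rings; a curve that never crosses yields
"not determined", a valid outcome. The default threshold is the fixed 1/7
criterion — the field's dominant convention — with 3σ and half-bit
per-ring criteria available. When only a single image exists, it is split
into complementary checkerboard pixel sets reassembled on half-resolution
grids (x spacing doubled, which keeps the two axes' frequency sampling
identical); whether a published FRC figure used two acquisitions or a
single-image split is generally unstated, so both entry points are
provided. Single-image splits share noise between half-images less than
two acquisitions would, so their FRC is optimistic at high frequency —
a known limitation of all checkerboard splits.

The band-limit oracle in the tests constructs two images sharing a signal
strictly below a cutoff f₀ (placed at a ring center, with noise of the same
scale as the signal) and asserts that the threshold crossing lands within
one ring of f₀; Hann leakage makes the crossing land just above the edge,
which is why the edge is aligned to the analysis grid rather than the
tolerance being widened.

## Expression statistics

Comparative-Cq fold induction averages replicate Cq values per sample,
forms ΔCq = Cq_target − Cq_ref (reference GAPDH), ΔΔCq between group means,
and fold = 2^−ΔΔCq with the control at 1. Replicates are averaged before
ΔCq (standard practice; per-replicate folds would weight noisy replicates
differently). Amplification-efficiency correction is out of scope. The
plate-array normalization subtracts the blank well, divides by the
blank-corrected GAPDH signal of the same group, and reports percent of the
control group's normalized value; pooled-sample semantics (one normalized
value per gene and group) is used since plate arrays are typically run on
pooled cDNA. Group comparisons use the classic pooled-variance Student
t-test (two-sided) — matching the method's usual naming — with Welch
available by flag, and stars assigned with `≤` thresholds (\*, \*\*, \*\*\*
for p ≤ 0.05, 0.01, 0.001). No multiple-testing correction is applied by
design; add one downstream if many genes are screened.

## The phantom generator: what it does and does not emulate

Because no reference images ship with the package, every imaging stage is
validated against synthetic stacks with analytic ground truth. A phantom
nucleus is a rotated solid ellipsoid (semi-axes r1 ≥ r2 ≥ r3 in µm) whose
interior is modulated by a chromatin-like texture — a Gaussian random field
smoothed to a 400 nm correlation length and rescaled to [1−a, 1+a],
a = 0.2 by default — then convolved with an anisotropic Gaussian PSF
(σ = 300/130/130 nm, a generic confocal-like blur) and corrupted by
Gaussian read noise (σ = 0.02) with optional Poisson shot noise. Ground
truth is analytic: V = 4/3·π·r1·r2·r3, surface area by Gauss–Legendre
quadrature of the parametric surface element (accurate to ≪ 1e−8), E =
r1/r2, density equal to the specified interior level. No intensity
statistics of real Hoechst stacks were available to fit, so these defaults
are declared, not estimated.

The two-group population generator states the contrast the pipeline is
meant to resolve: group A with mean volume 638 µm³, elongation 1.34 and
density 0.254; group B smaller (486 µm³), more elongated (1.86) and denser
(0.319), each with SDs of 50 µm³, 0.15 and 0.03 at n = 20 per group —
values chosen to mirror the study contrast the pipeline targets, with SDs
set to realistic within-group spreads for G1-gated nuclei. Volume and
elongation are converted to semi-axes through a fixed flatness ratio
r3/r2 = 0.65 (adherent interphase nuclei are oblate-ish); orientations are
uniform. Sampling is truncated-normal at the physical bounds V > 0, E ≥ 1,
D > 0.

What a green test establishes: the measurement stages recover known
geometry and intensity from realistically blurred, noisy, anisotropically
sampled data, and the group statistics detect the configured effect sizes.
What it does not establish: performance on real chromatin texture
(nucleoli, lamina-associated domains are not modeled), on dense tissue-like
nucleus packing beyond pairwise touching, or on STED photophysics; and the
published absolute values of compactness and chromatin density cannot be
reproduced without the original raw data, so only property-based checks
and direction-of-effect contrasts are claimed.

### Known measurement biases

PSF blur moves signal across the mask boundary, biasing chromatin density
downward by a few percent for ~5 µm nuclei and more for smaller ones (the
README example shows the effect); volumes from ground-truth masks are
essentially unbiased, and moment-based radii are accurate to < 3% at the
default spacing. The parameter-recovery test therefore asserts group means
within 2 standard errors of the generator's means — the density bias sits
inside that band at the stated world's effect sizes, and the test would
honestly fail if it did not.

## Numerical details worth knowing

- Distance transforms use the exact Felzenszwalb–Huttenlocher algorithm
  with per-axis sampling weights (physical units for radial profiles,
  isotropic voxel units for watershed seeds, per the merge rule's phrasing).
- Convolutions are separable with symmetric (reflecting) boundaries;
  derivative kernels are normalized to respond exactly 0 to constants and
  exactly 1 to unit ramps/quadratics, so flat-field tests are exact.
- The watershed priority queue breaks ties first-in-first-out, making label
  assignment deterministic.
- Degenerate inputs error early and explicitly: empty labels, coplanar
  voxel clouds (no ellipsoid), labels thinner than 2 voxels on any axis (no
  mesh), reference-gene signal at or below blank, single-class annotations.
- Seeds: every stochastic stage (phantom rendering, forest training,
  subsampling) is reproducible from a single integer seed.

## Command line

`exec/nucleomorph` exposes the stages as subcommands — `phantom`,
`segment`, `measure`, `frc`, `stats` — whose files compose: `phantom`
writes TIFF stacks and a ground-truth CSV, `segment` turns a stack and a
trained model into a label TIFF, `measure` turns stack + labels (+ optional
CDT1 and profile-marker channels) into a morphometry CSV, and `stats`
consumes morphometry or Cq CSVs. A YAML configuration file mirrors
`pipeline_config()`; every flag overrides it.
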
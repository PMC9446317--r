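---
title: "Lesion shape morphometry and AF association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion shape morphometry and AF association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators, and design decisions
behind `lesionshape`: how the six lesion shape descriptors are computed
from a binary mask, how lesion location is classified, how the
association with atrial fibrillation (AF) is modelled, and what the
synthetic-data module does and does not emulate.

## Segmentation

Acute ischemia restricts water diffusion, so acutely infarcted tissue
has a low apparent diffusion coefficient (ADC). `segment_adc()` labels a
voxel as lesion when all three hold: it lies in the brain mask, its ADC
is strictly positive, and its ADC does not exceed the threshold
(default 620 × 10⁻⁶ mm²/s).

Three conventions are deliberate and configurable:

* **The threshold is inclusive** (≤). A "maximum threshold" is read as
  an attained upper bound, matching common ADC-thresholding practice;
  boundary voxels are rare and the choice is documented rather than
  consequential.
* **ADC ≤ 0 is invalid background.** Zeros arise from masking and
  padding; letting them pass would pull air and CSF artifacts into the
  lesion.
* **"Smaller than 10 mm³" is strict.** `remove_small_components()`
  removes components whose physical volume is < 10 mm³; a component of
  exactly 10 mm³ survives. The filter uses the same connectivity as the
  component count (26 by default) so the two can never disagree about
  what a component is.

Manual rater corrections enter through `apply_manual_edits()`, which
validates shape and binarity, returns the edited mask verbatim, and
records how many voxels were added and removed.

## The six descriptors

All descriptors are computed in native voxel space from the mask and its
physical spacing; nothing assumes isotropic voxels.

**Components.** Connected components under 26-connectivity by default:
lesion masks are sparse and anisotropic, and the permissive adjacency is
the conventional choice; 6 and 18 are available. Labeling order is
deterministic (grid scan order), so outputs are reproducible
voxel-for-voxel.

**Volume.** Voxel count × voxel volume; reported in mL with
1 mL = 1000 mm³ fixed.

**Surface area.** Two estimators:

* The default `mesh` estimator mollifies each component's binary image
  with a small Gaussian and triangulates the 0.5 iso-surface by marching
  tetrahedra (6-tetrahedra cell decomposition, linear edge
  interpolation, spacing-aware vertex coordinates). Mollification is the
  step that makes the estimator convergent: the iso-surface of the raw
  binary field tracks the voxel staircase and overestimates a sphere's
  area by roughly 28%, while the face-count estimator overestimates it
  by roughly 50% — both factors are themselves computed in the test
  suite. The bandwidth is scale-adaptive: σ = min(0.625, r_eq/6) voxels,
  where r_eq is the component's volume-equivalent radius in voxels. The
  cap (5/8 voxel) suppresses the staircase with minimal erosion for
  large components; the r_eq/6 scaling protects small components, for
  which a fixed bandwidth comparable to their radius would shrink the
  iso-surface drastically. The rule was calibrated once against
  rasterized spheres of radius 2–20 voxels, for which the closed-form
  area 4πr² is the oracle; the acceptance suite re-verifies the sphere
  identity at radius 20 voxels. Components are meshed independently on
  cropped subgrids so nearby components cannot blur together; if a very
  small component still falls below the iso-level, its σ is halved until
  a surface appears (a single voxel ultimately meshes un-mollified).
* `face_count` sums exposed voxel faces × face area. It is exact for
  axis-aligned boxes (a 1 mm³ voxel scores exactly 6 mm²) and is kept as
  a comparison estimator, not for the shape factor.

**Oriented minimum bounding box.** One box over all components jointly,
so multifocal, widely dispersed lesions score a large OBB volume even
when each component is small — this is the descriptor that carries the
"scattered embolic pattern" signal. Voxels are treated as solid cuboids:
the box must contain all eight corners of every lesion voxel. That
convention keeps the fill ratio ≤ 1, gives a single voxel a well-defined
box, and makes the box physically interpretable as enclosing the imaged
lesion rather than its sampling points. The search:

1. collects the corner points of boundary voxels (identical hull to all
   corners), 2. reduces them to convex-hull vertices with an exact
   incremental hull (C++; clouds above 30k points are first thinned to
   directional extremes along 8192 directions), 3. scans a global
   orientation grid at 2° — orientations are parameterized by one box
   axis on a hemisphere (lat-lon) plus an in-plane angle modulo 90°,
   which covers every distinct box frame — seeded additionally with the
   hull's principal axes and the identity, and 4. polishes each
   candidate on shrinking local grids down to 0.02°. Extents are
   measured on the hull vertices, which realize every directional
   extreme, so containment is exact even though the orientation is
   approximate. The identity candidate is never polished away, so the
   OBB volume can never exceed the axis-aligned bounding box.

A brute-force reference, `obb_volume_exhaustive()`, sweeps the full
orientation grid at 1° and then re-sweeps the winning cell at 0.1° and
0.01°, so its value reflects the true minimum rather than the grid
quantization; the test suite requires the production search to agree
with it within 1% on rotated rasterized cuboids. One caveat established
while validating: a rasterized axis-aligned cuboid is exactly tight
(its voxel corners land on the continuum box), while any generic
orientation inflates the box by up to about one voxel per axis, so
rotation-invariance of the OBB volume is a property of generic
orientations and adequate resolution, not of the lattice-aligned pose.

**Fill ratio.** V / OBB volume, in (0, 1].

**Shape factor.** S = √A / V^(1/3) / C with V in mm³ and
C = √(4π)/(4π/3)^(1/3) = 2.199085233, the sphere's value of √A/V^(1/3).
S is scale-free, equals 1 for a perfect sphere, and grows with surface
complexity and elongation. S is meaningful only with a convergent area
estimator — with the face-count estimator a sphere would score
√1.5 ≈ 1.22 purely from digitization bias, which is why `mesh` is the
default and the sphere identity S = 1.00 ± 0.05 is an acceptance
check.

## Lesion location

`locate_lesion()` counts lesion voxels per atlas label and aggregates
them into three class families declared by the atlas label table:
hemisphere (left/right), vascular territory (left ICA, right ICA,
basilar), and cortical. A family member is affected when its aggregated
count reaches `min_voxels` (default 100); hemisphere becomes `both` and
territory becomes `multiple` when two members qualify. The 100-voxel
rule is applied uniformly to all three families, and counts are
aggregated over all labels of a class before thresholding ("any cortical
region" is a class-level statement). Lesions that reach the threshold
nowhere keep their argmax class but are flagged `below_threshold`, so
cohorts keep their size and downstream analyses can exclude flagged rows
explicitly. The threshold is applied in atlas-grid voxels; masks must
arrive registered to the atlas grid (registration is out of scope).

## Association analysis

`prepare_features()` natural-log-transforms the six shape descriptors
(they are strongly right-skewed) and z-scores them over analyzed rows;
age and NIHSS are z-scored without the log (clinical scores are not
positive-scale quantities, and a per-SD odds ratio near 2 for age is
only interpretable on the standardized scale); binary indicators pass
through. After preparation every continuous coefficient is a log odds
ratio per SD, so effect sizes are comparable across variables. The log
base is irrelevant after standardization; natural log is fixed for
reproducible intermediates.

Models are maximum-likelihood logistic fits (`glm`, binomial), with Wald
95% intervals and p-values — the default of standard GLM practice when
only OR + CI are reported. Complete separation is detected (absent or
exploding coefficients/standard errors) and raised as an error naming
the variable. The multivariate shape model contains components, volume,
sphericity, OBB volume, and fill ratio; **surface area is excluded** as
collinear with volume (on the log scale the two are nearly affine).
Rank-deficient designs are an error listing the collinear columns.

`stepwise_eliminate()` iterates: fit, find the largest Wald p; if it
exceeds α (default 0.05) remove that variable and refit; stop when all
survivors are significant or nothing remains. Ties in the maximal p are
broken by input variable order, making the trace deterministic. An
emptied model is returned as intercept-only with a flag. Stepwise
selection inherits the usual caveats (selection noise, optimistic final
p-values); it is implemented as specified, and the test suite measures
its behaviour on cohorts with known structure rather than assuming it.

`compare_groups()` uses the two-sided Mann–Whitney test with the
normal approximation and tie correction for continuous variables
(medians + IQR reported per group) and the chi-squared statistic with a
Monte-Carlo p-value for binary variables:
p = (1 + #{simulated χ² ≥ observed}) / (1 + B), simulating tables with
both margins fixed. B defaults to 10 000 and a seed is required; the
test suite checks the Monte-Carlo p against exhaustive hypergeometric
enumeration on small 2×2 tables. Missing values are handled by listwise
deletion per model, with n reported per fit.

## The synthetic-data module

The generators exist so every stage can be tested against known ground
truth without any patient data.

* `make_lesion_mask()` places disjoint rasterized spheres (radii uniform
  in 3–6 mm by default) around the grid centre with Gaussian scatter
  (`dispersion_mm`). Disjointness is enforced with a one-voxel dilation
  guard in the 26-neighbourhood, so the realized component count is
  unambiguous under any labeling connectivity; placement is bounded
  rejection sampling (default 1000 tries) that fails loudly rather than
  under-generating. Dispersion is our construct: it is the single knob
  that drives OBB volume at fixed component sizes, and the test suite
  verifies OBB volume is monotone in it on matched seeds.
* `make_adc_volume()` paints lesion 400 × 10⁻⁶ and background
  800 × 10⁻⁶ mm²/s (typical acute-infarct and parenchyma values, which
  straddle the 620 × 10⁻⁶ threshold symmetrically enough that noise of
  sd 50 × 10⁻⁶ leaves Dice ≥ 0.95) plus i.i.d. Gaussian noise.
* `make_toy_atlas()` partitions the grid by midplane (hemispheres), an
  anterior/posterior split (ICA territories vs basilar, posterior 30%),
  and a boundary shell (cortex). It is schematic by construction; the
  classifier only needs conforming labels.
* `simulate_cohort()` draws features from independent log-normal /
  normal / Bernoulli marginals calibrated to the descriptive statistics
  of an MRI-confirmed stroke cohort (e.g. median lesion volume 0.39 mL,
  IQR 0.13–1.13; median OBB 13 mL; AF prevalence 12.3%;
  sdlog = log(IQR ratio)/1.349), and the AF outcome from a logistic
  model whose default coefficients are the three-variable risk pattern
  used throughout: age OR 2.13 per SD, female sex OR 2.45, OBB volume
  OR 1.72 per SD, all other effects null. Coefficients act on
  population-standardized scales (for log-normals, (log x − μ)/σ), which
  is what the downstream per-SD odds ratios estimate.
* `simulate_study()` ties it together at image level: per-subject masks
  and ADC volumes plus clinical covariates, with AF depending on age,
  sex, and the z-scored log of the true component count (multifocality
  standing in for the embolic pattern at image level). Its atlas uses a
  thick cortical shell (one sixth of the grid) so dispersed lesions can
  plausibly reach "cortex".

What the generators deliberately do **not** emulate: brain anatomy and
tissue contrast, anisotropic clinical voxel grids (clinical slices of
3–6 mm are supported by the estimators but the default simulations are
near-isotropic), correlation between shape features (in real cohorts
volume and surface area are strongly collinear — the multivariate
model's exclusion of surface area is motivated by that reality, not
observable in the independent-marginal simulation), registration error,
or realistic territory frequencies (scattered synthetic blobs cross the
midline far more often than real single-embolus strokes). Green tests
therefore certify the estimators and the inferential machinery, not
clinical performance on patient data.

## Numerical choices and degenerate inputs

* Convex hull: incremental insertion, farthest-first; visibility
  tolerance 10⁻⁹ × cloud extent; coplanar points are interior, so
  rasterization grids do not generate sliver faces. All-coplanar input
  is an error (a mask always provides two voxel layers of corners).
* OBB: candidates are evaluated and compared on hull vertices; the
  identity frame guarantees OBB ≤ AABB; hull volume ≤ OBB is guaranteed
  by containment. Refinement windows (step, step/4, 0.1, 0.02 degrees)
  are fixed, not data-dependent, for determinism.
* Empty masks are errors in every descriptor (subjects without an acute
  lesion are excluded upstream with an explicit reason, and the pipeline
  asserts input subjects = output rows + logged exclusions).
* Zero-variance features and non-positive shape values are errors in
  `prepare_features()` rather than silent NaNs.
* All simulation entry points take integer seeds, restore the caller's
  RNG state, and are bit-reproducible; Monte-Carlo p-values require a
  seed.
* Small cohorts: the pipeline caps the multivariate model size by the
  events-per-variable rule (predictors ≤ half the minority class) and
  backs off deterministically if the fit still separates, down to an
  intercept-only model flagged as such — a 20-subject smoke cohort runs
  end to end without manual intervention.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make their
checks sharp but routine: calibration sphere of radius 20 voxels
(≈ 33 500 voxels); 50 rotated cuboids on ≤ 32³ grids against the 1°
exhaustive oracle; 50 random 9³ masks against a flood-fill oracle;
20-seed segmentation noise sweeps; cohorts of n = 2000 (100 seeds) for
stepwise behaviour, n = 500 (200 seeds) for CI coverage, and n = 5000
for calibration; a 60-subject imaging cohort in the analysis workflow
and 20 subjects for end-to-end determinism.

## Known limitations

* The mesh area estimator is biased low for components under ~2 voxels
  radius; such components contribute little area in absolute terms, and
  the shape factor of sub-voxel-scale structures should not be
  over-interpreted at any rate.
* The OBB search is approximate (grid + polish); the test suite bounds
  its error against the exhaustive oracle at 1% on small instances, but
  no global optimality certificate is produced.
* The lesion/OBB fill-ratio simulation marginal can exceed 1 (a
  log-normal tail), which real measurements cannot; the measured
  pipeline never produces it.
* Stepwise elimination is reported because it is the study's analysis of
  record;
  its known fragilities (nuisance-variable retention at modest n) are
  visible directly in the test suite's retention-rate measurements.
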
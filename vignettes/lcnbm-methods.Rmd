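---
title: "Methods: LC signal intensity, NBM volumetry and the phantom framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LC signal intensity, NBM volumetry and the phantom framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcnbm)
```

## Scientific background

The locus coeruleus (LC) and the nucleus basalis of Meynert (NBM) are the
principal nuclei of the brain's noradrenergic and cholinergic systems, and
both are vulnerable early in several neurodegenerative proteinopathies.
Neither can be measured like a cortical structure. The LC is a thin,
elongated brainstem nucleus of a few millimetres' width that appears as a
small hyperintense focus on neuromelanin-sensitive turbo-spin-echo (TSE)
T1 slabs, so its integrity is summarized as a *signal intensity*, not a
volume. The NBM has no intensity contrast of its own and is instead
measured as the native-space volume of a histology-derived atlas mask
warped into the subject's anatomy.

This package implements both measurements, the composite cortical VOIs
used alongside them, and the accompanying statistical plan, together with
a phantom generator that provides ground truth for every stage.

## LC signal intensity (LC-I)

Three boxes are defined on a brainstem template grid: a rostral
pontomesencephalic *reference* region with a target volume of 6200 mm³,
and one 700 mm³ box per side enclosing the coeruleus–subcoeruleus
complex, placed so that no other structure that would appear bright (such
as the substantia nigra) falls inside them. Exact volumes are unreachable
with whole voxels, so each box holds `round(target / voxel_volume)`
voxels laid out as a near-cubic cuboid whose last slice may be partially
filled; the achieved volume is within half a voxel volume of the target
(0.48 mm³ voxels at the default 0.4 × 0.4 × 3 mm TSE resolution). The
left and right boxes are exact mirror images about the grid's midsagittal
plane. Boxes are brought onto a subject's image by nearest-neighbour
pull-back through the inverse of the template-to-native transform, which
preserves disjointness by construction.

Within each LC box the LC area is found by a deterministic greedy search
for the *k = 10 brightest connected voxels*: seed at the box maximum,
repeatedly add the brightest voxel adjacent to the current set (26-
connectivity by default; 6 and 18 available), stop at *k* voxels. Ties
are broken by the smallest linearized voxel index, which makes the search
fully reproducible. The exact maximum-weight connected *k*-subset problem
is NP-hard; the greedy rule is the deterministic formalization of
"growing the brightest connected cluster", and an exhaustive reference
mode (`select_brightest_connected_exact`) is provided for very small
boxes and `k <= 6`. The search is run once per side — the natural reading
of one 700 mm³ box per side — rather than jointly across hemispheres.

The LC-I of a side is the mean intensity of its selected voxels
normalized by the mean intensity of the reference box. Two formulas are
offered because both are in use in the neuromelanin literature: `ratio`
(`m / r`, the default) and `contrast` (`(m − r) / r`). Both are invariant
under any positive global rescaling of the image, which is the point of
the normalization: it makes intensities comparable across subjects. The
reported LC-I is the mean of the two sides. Instead of a manual visual
check of voxel placement, each side carries automated QC flags (set size
equals *k*, set connected, set inside its box, centroid inside the box);
a side failing QC is excluded from the side average and flagged, and no
voxel is ever modified. A non-positive reference mean aborts the
computation, since it signals corrupted normalization.

## NBM volumetry

The subject's native-to-template normalization is assumed to be computed
upstream (registration itself is out of scope; transforms are inputs).
Its inverse — a template-to-native `deformation_field`, either a 4 × 4
affine, an affine composed with a smooth parametric displacement, or a
dense displacement field — is applied to the template NBM mask by
trilinear interpolation of the binary values followed by a 0.5 threshold.
Trilinear-plus-threshold was chosen over nearest-neighbour because it
gives smoother volume estimates under small deformations;
nearest-neighbour remains available by flag. Left and right volumes are
voxel count × voxel volume; the side average is normalized to
intracranial volume with the per-mil convention
(`vol_mean / ICV × 1000`), and raw mm³ values are always reported
alongside, with explicit units, since normalization conventions differ
between studies. ICV is a required cohort-table input (deriving it from
brain masking is out of scope). Bilateral masks are split into sides at
the midsagittal plane when side-labelled masks are not supplied.

No third-party atlas is shipped: `synthetic_nbm_template()` builds a
synthetic bilateral stand-in (two mirror ellipsoids of ≈350 mm³ per side
at 1 mm isotropic spacing, the scale of the real Ch4 cell group), and any
real mask can be supplied as a NIfTI path wherever the template is
accepted.

## Composite cortical VOIs

Regional statistics tables in the aparc/aseg dialect are parsed into a
per-subject region table. Composite thickness VOIs are the
surface-area-weighted mean of member-parcel thicknesses per hemisphere,
then averaged across hemispheres; area weighting is the standard
meta-ROI practice, and an unweighted mean is available because published
tables do not always state the weighting. Volume VOIs are per-hemisphere
sums, averaged across sides, with optional per-mil ICV normalization
matching the NBM convention. The shipped member lists (a temporal
meta-VOI — entorhinal, parahippocampal, fusiform, inferior and middle
temporal — plus lateral temporal, lateral parietal, medial parietal and
frontal lobar sets) live in an editable YAML file rather than code,
because the lobar memberships follow a convention, not a unique
definition.

## Statistical plan

Group differences are tested by ANCOVA: a linear model of the measure on
a two-group indicator plus age and sex, with listwise deletion and the
complete-case n always reported. The group term's t statistic and its
single-df F (= t²) are both returned. Collinear designs (e.g. a
single-sex group with a sex covariate) are refused rather than silently
dropped.

Associations are linear partial correlations: both variables are
residualized on an intercept plus the covariate columns (group entering
as dummy codes in pooled-patient analyses; age and sex for imaging
targets, age for cognitive targets) and the Pearson correlation of the
residuals is reported with `df = n − 2 − q`. Signed r, r², raw and
Bonferroni-adjusted p are all returned — the sign is scientifically
meaningful even where published tables print r² only. All tests are
two-sided.

The default plan declares five Bonferroni families with sizes 6 (LC-I
and NBM vs controls, 2 measures × 3 patient groups), 48 (8 other imaging
measures × 6 pairwise contrasts), 30 (5 cognitive scores × 6 pairwise
contrasts), 64 (2 predictors × 8 imaging targets × 4 analysis sets) and
a cognitive-correlation family whose declared size is a free plan
parameter defaulting to 48 while 2 × 5 × 4 = 40 tests are computed: the
printed family size in the motivating analysis does not factor into the
plan's natural dimensions, so the package declares the published size
(Bonferroni over a larger declared family is conservative, never
anticonservative) instead of guessing a composition. A machine-readable
manifest reports declared and computed counts per family.

## The phantom generator

The generator provides ground truth for three different kinds of checks.

*LC phantoms.* A TSE-like slab (default 256 × 256 × 20 voxels at
0.4 × 0.4 × 3 mm; the slab's field of view is not a published quantity,
so it is a configurable grid) holds a uniform background (100 intensity
units), one compact connected cluster per LC box at the group's target
contrast ratio, optional bright distractors outside all boxes (to
exercise the premise that box placement, not the search, avoids other
bright structures), and additive Gaussian noise (SD 2, i.e. 2% of
background; a Rician option reflects real magnitude images, but Gaussian
keeps closed-form checks simple and is the default). Clusters are
rasterized as the n box voxels closest to the box centroid under an
elongated ellipsoidal metric (the LC runs rostro-caudally); the default
cluster size is 20 voxels so that the k = 10 search must select a strict
subset, and setting it to 10 makes the truth set exactly recoverable.
Subject transforms are whole-voxel translations, so resampled boxes keep
their voxel counts exactly.

*NBM phantoms.* The template-to-native deformation is an isotropic
scaling at the group's scale factor (with 3% log-normal between-subject
jitter) about the mask centroid, composed with a divergence-free
sinusoidal displacement with random phase. Because the sinusoid is
divergence-free it preserves continuum volume, so the expected volume
change is exactly the cube of the scale factor — which is what the
analytic recovery tests check. Its amplitude (0.3 mm, wavelength 16 mm)
is deliberately kept in the regime where binarized trilinear warping is
self-consistent (mask → native → template round trips with Dice > 0.99);
at amplitudes approaching half a voxel the interpolation smoothing, not
the field, dominates the round-trip error. The amplitude bound
`a < wavelength / (2π)` guarantees invertibility, and inverses are
computed by fixed-point iteration to 10⁻¹⁰.

*Cohort tables.* Covariates follow the four-group study conditions the
package targets (groups Control/AD/LATE/FTD with n = 15/23/17/17; group
age means 68.7/70.4/77.3/70.1 years with SDs 3.6/6.5/5.2/8.6; male
fractions 5/15, 12/23, 11/17, 9/17; LC-I missing in 1 LATE and 5 FTD
subjects, mirroring technical failures). Measures and cognitive scores
are drawn from a joint Gaussian: group mean + age slope × (age − 70) +
correlated residual, where the residual correlation matrix is assembled
from user-specified partial-correlation targets (given group, age and
sex) and checked for positive definiteness at design construction.
Cognitive group means and SDs sit on the scales of a standard dementia
battery (MMSE /30, Mattis /144, memory /96, parietal /188, executive);
scores are generated unbounded — no ceiling at the instrument maximum —
because truncation would distort the correlation calibration, and
truncated variants can be layered on by the user. LC contrast ratios per
group (1.30 control, 1.18 AD/LATE, 1.22 FTD — the FTD alteration being
slightly less marked) and NBM scale factors (1.00/0.85/0.85/0.87) are
not published quantities; they were fixed once at values producing
realistic effect magnitudes and are stated here so that simulation
results are interpretable.

What the phantoms deliberately do *not* emulate: anatomy (boxes enclose
synthetic ellipsoids, not a pons), registration error (transforms are
exact by construction), Gibbs ringing/bias fields, realistic cortical
surfaces (regional tables are generated directly as numbers), or
bounded test scores. Passing phantom tests therefore demonstrates that
the *computational* pipeline is correct and calibrated under its own
assumptions — not that the acquisition or registration steps of a real
study are.

## Numerical choices and degenerate inputs

* Tie-breaks: everywhere by smallest linearized voxel index (x fastest).
* Threshold comparisons: mask binarization uses `>= 0.5`.
* Fixed-point inversion: tolerance 10⁻¹⁰, at most 100 iterations;
  contraction is guaranteed by the construction-time amplitude bounds.
* Empty boxes, empty warped masks, non-finite intensities, non-positive
  reference means, non-positive ICVs, singular affines, non-positive-
  definite correlation targets and clusters larger than their box are
  all hard errors naming the offending object; an undersized selected
  set is a QC flag, not an error, because it is a property of the data
  rather than a misuse of the API.
* A side that fails QC is dropped from the LC-I side average and
  flagged; the valid side is still reported.

## Problem sizes used by the test-suite simulations

Simulation-based checks run on reduced problem sizes chosen to keep the
suite quick while leaving every geometric constant intact: phantom slabs
of 112 × 112 × 20 voxels (default-resolution checks) or 52 × 52 × 10
voxels at 0.8 × 0.8 × 3 mm (the 500-replicate power study; the box
construction rule is resolution-independent, so the 6200/700 mm³ targets
are still honoured), 2000 null cohorts for the type-I calibration,
n = 5000 for partial-correlation recovery, and a 40-subject cohort for
the byte-level determinism check. The defaults of `phantom_design()`
are never changed by the tests.

## Known limitations

* The greedy search is not the exact maximum-weight connected k-subset;
  on adversarial intensity patterns the two differ (the exact mode
  exists for auditing small cases).
* Volumes from binarized trilinear warping carry a surface
  discretization error of up to ~2% for structures of NBM size at 1 mm
  spacing; round-trip self-consistency degrades as displacement
  amplitudes approach half a voxel.
* The statistical layer implements the fixed published families; it is
  not a general multiple-testing framework (no FDR, no mixed models).
* Manifest-driven runs assume axis-aligned grids with the voxel-centre
  world convention used throughout the package; oblique acquisitions
  must be resampled upstream.

## A worked example

```{r example, eval = FALSE}
design <- phantom_design(n_per_group = c(Control = 10, AD = 10,
                                         LATE = 10, FTD = 10),
                         tse_grid = c(112, 112, 20), seed = 11)
run <- run_pipeline(run_config(design = design, out_dir = "lcnbm-out",
                               seed = 11))
run$results$manifest
tapply(run$cohort$lc_i, run$cohort$group, mean, na.rm = TRUE)
```
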
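---
title: "Quantifying morphological change of intracerebral hematomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying morphological change of intracerebral hematomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemomorph)
```

## The problem

When a patient with spontaneous intracerebral hemorrhage (ICH) gets an
initial and a repeat CT scan, the hematoma may have grown — hemorrhage
expansion, conventionally an increase of at least 6 mL or 33% — but it
may also have *changed shape*: become more irregular, elongated along a
particular anatomical axis, or drifted from its original position.
`hemomorph` quantifies these morphological changes from paired,
co-registered 3D binary hematoma masks, aggregates them over a cohort,
and feeds them into a prognostic logistic model for poor outcome
(Glasgow Outcome Scale ≤ 3).

All grids live in RAS orientation: +x right (left–right, LR), +y
anterior (anterior–posterior, AP), +z superior (superior–inferior, SI).
With patients supine, gravity points along −y.

## Per-scan metrics

**Volume** is the foreground voxel count times the voxel volume,
reported in mL.

**Surface area and the SR index.** Shape irregularity is measured by
the surface regularity index

$$\mathrm{SR} = \frac{\pi^{1/3}\,(6V)^{2/3}}{A},$$

with $V$ the volume (mm³) and $A$ the surface area (mm²). SR is 1 for
a perfect sphere (the isoperimetric optimum), decreases toward 0 as the
surface grows relative to the volume, and is invariant to overall
scale. The delicate quantity is $A$: counting exposed voxel faces
overestimates the area of smooth shapes by roughly 50% (a sphere would
score SR ≈ 0.67), and even a triangulated iso-surface of the raw 0/1
indicator is a staircase that overestimates by several percent. The
package therefore

1. crops the mask to its foreground bounding box (so padding never
   matters), zero-pads it,
2. smooths the indicator with a small Gaussian, σ = 0.6 mm by default,
   floored at 0.6 voxel per axis so anisotropic slices are resolved,
3. doubles the grid once by trilinear interpolation, and
4. extracts the level-0.5 surface by marching tetrahedra (six
   tetrahedra per lattice cube, crossing points linearly interpolated)
   and sums the triangle areas, scaled by the voxel spacing per axis.

Calibrated on analytic phantoms, this estimator is accurate to about
+1% to +3% on voxelized spheres of radius ≥ 10 voxels and about −5% on
a 20 mm cube (smoothing necessarily rounds sharp edges slightly;
larger boxes do better). Voxelized spheres score SR between 0.95 and
1.05. The σ default trades sphere accuracy against edge rounding; it is
exposed in `pipeline_config()` for users whose lesions are unusually
small or whose slices are unusually thick.

**Diameters.** The three diameters are measured on maximum-area slices
in the standard planes, parallel to the coordinate axes: AP and LR are
the foreground extents along y and x on the axial slice with the
largest in-plane area; SI is the extent along z on the maximum-area
coronal slice. Two conventions are declared rather than derived:

* the SI plane is coronal by default (axial slices cannot yield an SI
  extent); sagittal is available via `pipeline_config(si_plane =)`, and
  for axis-aligned lesions the two agree;
* an extent counts both boundary voxels, `(max − min + 1) × spacing`,
  so a single voxel has nonzero physical size;
* slice-area ties are broken toward the lowest slice index.

**Axis type.** The longitudinal axis type is the axis of the longest
diameter — AP, LR or SI — unless all pairwise diameter ratios fall in
the similarity band [0.850, 1.176] (endpoints inclusive), in which case
the hematoma is "NL", no longitudinal axis, i.e. roughly spherical.
Exact ties between longest diameters are broken by the priority
AP > SI > LR, the frequency order of axis types in real cohorts; such
ties have measure zero but the classifier must be deterministic.

## Paired-scan metrics

**Length and direction change.** Length changes are signed
repeat-minus-initial differences per axis. The direction change is the
axis with the largest absolute change; it is "none" when the largest
change is under 1 mm (`no_change_eps_mm` — below measurement noise a
direction is meaningless) or when the two largest absolute changes are
similar. "Similar" has no published numeric criterion; this package
reuses the diameter similarity band (second largest / largest ≥ 0.850).
Both knobs are config-exposed, and the choice is flagged here rather
than buried: with a different similarity rule the "no direction change"
fraction will shift.

**Center movement.** The geometric center is the centroid of the
largest 26-connected foreground component, mapped to world mm.
26-connectivity is used because hematomas are blob-like and face-only
connectivity fragments thin diagonal bridges. Movement is the
repeat-minus-initial vector, its Euclidean norm, and its projections
onto the axial, coronal and sagittal planes.

**Expansion and screening.** Expansion is inclusive: absolute increase
≥ 6 mL *or* relative increase ≥ 33%. Pairs whose repeat volume is
below 3 mL, or whose volume decreased by more than 3 mL, are flagged
for exclusion (both bounds strict, so the boundary cases stay in);
such lesions are resolving rather than expanding and their shape
change is not comparable.

**Registration QC.** Masks are assumed co-registered; the registration
itself is out of scope. Quality control is a Dice coefficient against
the threshold 0.93, inclusive. `pair_report()` reports the pair's own
overlap Dice descriptively, and takes the upstream registration Dice as
an optional argument for the QC flag; when absent, QC is recorded as
assumed-pass and flagged `qc_assumed`.

## Cohort-level analysis

Summaries report counts (%) for categorical variables and mean (SD) and
median (IQR) for continuous ones. The IQR is a single width, Q3 − Q1,
under the default type-7 (linear interpolation) quantile rule — IQR
widths depend on the rule, so it is stated.

Subgroup tests follow the standard clinical menu with a declared
selection rule: chi-squared for categorical variables, Fisher's exact
test when any expected cell is below 5; for continuous variables a
Shapiro–Wilk screen at α = 0.05 in each group routes to the t-test /
ANOVA when no group rejects normality and to Mann–Whitney /
Kruskal–Wallis otherwise. The selection is a pure function of the data.

Region-wise direction synthesis averages *unit* vectors per anatomical
region: the mean unit vector is the synthesized direction, its norm
(the resultant length, in [0, 1]) measures how concentrated the
directions are, and mean distance is reported separately. Direction-only
averaging is the default because a synthesized arrow should answer
"where do hematomas in this region drift", not "how far";
magnitude-weighted averaging is available via `weight = "distance"`.
Zero-length vectors carry no direction and are excluded from the
average (but kept in the distance mean).

## The prognostic model

Predictor selection fits **one** multivariable logistic model on all
candidates and retains those with Wald p < 0.05. The alternative
reading — stepwise selection — is available behind
`method = "stepwise"` (backward AIC), but the single full fit is the
default: it is deterministic, simpler to report, and does not inherit
stepwise's order dependence. The candidate list is an argument, not a
constant, since candidate sets vary by site and data availability.

The final model reports odds ratios $e^\beta$ with Wald intervals
$e^{\beta \pm 1.96\,\mathrm{SE}}$, discrimination as the ROC AUC with a
DeLong-variance interval (no method is canonical in the clinical
literature; DeLong is the common default), and calibration as a decile
table of mean predicted risk versus observed event rate, with
tie-emptied bins merged and flagged. Fits that show (quasi-)separation
or fail to converge raise an error rather than returning unstable
coefficients; the nomogram is reported as this coefficient table, not
a rendered graphic.

## The synthetic generator

No patient-level imaging is distributable, so every stage is exercised
on seeded phantoms with analytic ground truth.

A lesion is an ellipsoid with semi-axes $(r_x, r_y, r_z)$ whose radial
boundary is modulated as $1 + a\,g(u)$, where $g$ is a sum of
`n_bumps` randomly oriented cosine lobes on the unit sphere with
$|g| \le 1$ and $a \in [0, 1)$ is the irregularity amplitude; $a = 0$
reduces exactly to the ellipsoid. The repeat lesion applies per-axis
growth factors about the center and a displacement — and because the
perturbation is defined on the ellipsoid's angular coordinate, the
repeat lesion is exactly the affine image of the initial one: the
volume ratio is exactly the product of the growth factors and each
axis-aligned extent scales by its factor. That is what makes diameter,
volume-ratio and translation recovery assertable to tight tolerances.

`make_cohort()` draws a whole cohort. Its defaults emulate the
structure of a large multicenter ICH cohort: lognormal semi-axes with
AP typically longest and median volume ≈ 20 mL; a shared lognormal
growth factor with per-axis jitter giving expansion in roughly a
quarter to a third of cases (and enough shrinking lesions to exercise
the exclusion screen); a planted displacement bias of 3 mm toward −y
(gravity, supine) with 1 mm isotropic noise; age median 61, ~64% male,
GCS median 14, location mix ≈ 70/22/9% deep/lobar/subtentorial, IVH
34%. Poor outcome is generated from a logistic model with fixed known
coefficients on age (+0.03/y), volume (+0.035/mL), GCS (−0.28/point),
expansion (+0.7), lateral diameter change (+0.13/mm, an odds ratio of
≈ 1.139 per mm of lateral expansion) and subtentorial location (+0.6);
sex, IVH and the timing variables carry no effect, so selection has
true negatives to reject. All randomness flows from the single seed.

What the phantoms do *not* emulate: real hematomas are far rougher
(finger-like projections, satellite fragments, intraventricular
extension) than smooth perturbed ellipsoids — cohort SR values here run
higher than the ~0.54 typical of clinical series; registration error,
partial-volume effects and segmentation disagreement are absent; and
lesion location is a label, not a position in an atlas. Passing tests
therefore establish that the *measurement pipeline* recovers known
geometry and known statistical structure, not that any clinical finding
generalizes.

## Problem sizes and runtime choices

The default generator grid is 128³ at 1 mm isotropic — desk scale
(well under a second per case) while keeping voxelization error inside
the stated tolerances (volume within 2% for semi-axes ≥ 8 voxels). The
bundled analysis scripts simulate 200 patients and run the full
measured pipeline in a couple of minutes; the test suite uses cohorts
of 50–100 rasterized cases and up to 10⁴ random triples or 5000-row
simulations for the statistical components. Oversized tail lesions are
shrunk to keep the grown, perturbed repeat scan inside the grid with a
safe margin.

## Known limitations

* Diameters are axis-aligned projections measured on maximum-area
  slices; an oblique lesion's true longest axis is only approximated by
  the nearest coordinate axis.
* The surface estimator's smoothing rounds genuinely sharp ridges; for
  lesions under ~8 voxels across, SR values are not reliable.
* The "similar length change" rule behind "no direction change" is a
  declared surrogate for an unpublished criterion.
* Ground-truth diameters are exact only for unperturbed ellipsoids; for
  perturbed lesions the generator records the nominal (unperturbed)
  values.
* The prognostic model assumes independent observations and complete
  cases; no multi-center clustering, imputation or external validation
  is implemented.
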
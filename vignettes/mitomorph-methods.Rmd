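---
title: "Methods: 3D morphometry of mitochondria and cristae on anisotropic voxel grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry of mitochondria and cristae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Serial block face-scanning electron microscopy (SBF-SEM) images the freshly
cut block face between automated ultramicrotome passes, yielding aligned
serial sections from which organelles can be manually segmented and
reconstructed in 3D. The resulting data are *instance label volumes*: 3D
integer grids in which each mitochondrion (or each crista) carries its own
label and 0 is background. Two properties of such data drive every design
decision in this package:

* **Anisotropy.** In-plane pixels are much finer than the section thickness
  (nominally 10 × 10 nm in x/y versus 50 nm in z). Every geometric
  computation must work in physical coordinates, not voxel counts.
* **Two co-registered segmentations.** Mitochondria and their cristae (the
  invaginations of the inner membrane that house the oxidative-
  phosphorylation machinery) are traced independently, so cristae voxels
  are *near*, but not exactly, subsets of their parent mitochondrion.

From these volumes the package computes, per object: volume, surface area,
a slice-wise perimeter, sphericity, and the mitochondrial complexity index
(MCI); per crista: the same metrics normalized by the parent
mitochondrion's volume; per mitochondrion: cristae density and matrix
volume; and, across two experimental groups (here: adult vs aged brown
adipose tissue), object-level and animal-level comparisons with standard
errors and significance stars, plus volume-binned "otyping" galleries of
representative shapes.

## Shape metrics

For an object of volume $V$ and surface area $SA$:

$$\psi = \frac{\pi^{1/3}\,(6V)^{2/3}}{SA}, \qquad
  MCI = \frac{SA^3}{16\pi^2 V^2}.$$

Sphericity $\psi$ is 1 for a perfect sphere — the isoperimetric maximiser —
and decreases for elongated or branched shapes; MCI is its complexity-
increasing counterpart (9/4$\pi$ ≈ 0.716 for a sphere, larger for branched
networks). Both are invariant under isotropic rescaling, so objects with
the same shape but different sizes score identically. The two formulas are
algebraically locked together:

$$MCI \cdot \psi^3 = \frac{9}{4\pi}$$

for *any* positive $V, SA$. The package asserts this identity to $10^{-12}$
for every emitted row — it is a free end-to-end consistency check on the
metric plumbing (any unit slip between the two breaks it).

## Estimators and their numerical behaviour

**Volume** is exact: voxel count × voxel volume. On digitized spheres of
radius ≥ 0.2 µm at the default spacing the relative error is below 1%.

**Surface area** is the hard one. Counting exposed voxel faces
overestimates a sphere's area by ~50% (the staircase never flattens), and
meshing the *raw* binary mask at the 0.5 level still overestimates by
~36%. The package therefore smooths the binary occupancy with a small
Gaussian (σ = 1 voxel per axis) and meshes the 0.5 iso-surface of the
smoothed field by marching tetrahedra with spacing-aware vertex placement.
On analytic test shapes this estimator lands within ~4% for digitized
spheres and ~2% for cubes; the voxel-face count is retained as a strict
upper-bound oracle in the tests. σ = 1 voxel was chosen on analytic
phantoms as the smallest smoothing that tames the staircase bias while
keeping 2-voxel-thin structures (thin cristae slabs) above the 0.5 level;
objects that still fall below the level after smoothing are re-meshed on
the raw field, and single voxels fall back to their face area (both
flagged).

**Perimeter** is reported by the upstream reconstruction tools without a
published definition, so the package defines it operationally and
documents it: per z-slice, the polygonal contour length of the 2D
cross-section at the 0.5 level of the (2D-smoothed) slice, scaled by the
in-plane spacing, then reduced across the slices containing the object by
the *mean* (sum and max are exposed as options). The slice-wise mean is
resolution-stable and anisotropy-aware. Smoothing matters here too: raw
binary marching squares overestimates a digitized circle's circumference
by ~5.5%, the smoothed contour is within ~1%.

**Connectivity** follows the standard digital-topology pairing: foreground
26-connected, background 6-connected. Objects touching the volume
boundary are flagged, never silently dropped, since reconstructions live
inside fixed blocks; exclusion is an option. A `min_voxels` threshold
(default 10) suppresses segmentation specks and is logged.

## Cristae nesting and normalized metrics

Each crista is assigned to the mitochondrion containing the plurality of
its voxels, provided that overlap reaches 0.5 (ties break deterministically
toward the lower id). Per-crista volume, surface area and perimeter are
divided by the *parent's* volume — per-crista rather than cohort-pooled
normalization, because the distributions being compared are per-structure.
Cristae density is $\sum$ cristae volume / mitochondrion volume, and
matrix volume is the complement (mitochondrion − cristae), computed as a
set difference *by volume* so that one-voxel registration slack between
the two segmentations cannot produce negative matrix estimates. The
conservation identity matrix + cristae = mitochondrion holds by
construction, up to one ulp of double rounding.

Cristae *scores* (ordinal 1–4 ratings of cristae normality, assigned
blinded: 1 = minimal normal cristae, 2 = <50% normal, 3 = 50–75% normal,
4 = normal) are ingested annotations, never computed from geometry — the
score is a human qualitative call and automating it would be invention.
Multiple blinded raters are combined by the median with half-valued ties
rounded *down*, i.e. toward the worse call: conservative and safe for
ordinal data. Treating the mean score as interval-scaled for the group
comparison mirrors common practice; the rank-sum p-value is always
reported alongside.

## Statistical layer

Object-level inference is primary (the figure panels compare ~300
structures per cohort); per-animal means are reported alongside as the
hierarchical caveat, not folded into a mixed model. The default test is
Welch's unequal-variance t (group variances demonstrably differ in the
aged condition); classical pooled-variance Student's t is available by
flag. "Non-parametric where applicable" is operationalized as: a
Shapiro-Wilk screen at α = 0.05 on either sample (Anderson-Darling above
n = 5000) switches the primary p-value to the Mann-Whitney rank-sum test —
and both tests' p-values are always recorded, so the choice is
transparent. Stars follow the strict thresholds * p < 0.05, ** p < 0.01,
*** p < 0.001, **** p < 0.0001 (p = 0.05 exactly is `ns`). No
multiple-testing correction is applied by default, matching per-figure
testing practice; `p_adjust` accepts any `stats::p.adjust` method.
Heterogeneity is summarized as within-animal coefficients of variation and
the between-animal CV of animal means.

## The synthetic cohort generator

No public volumes accompany the study design this package targets, so the
generator is first-class, tested code that plants known truth:

* **Study conditions.** Two groups ("adult", "aged"), 3 animals per group,
  100 mitochondria per animal (≈300 per cohort), 10 × 10 × 50 nm voxels.
* **Shape families.** Spheres; randomly oriented prolate spheroids (the
  "oval" low-thermogenic morphology; spheroids rather than triaxial
  ellipsoids so the attached surface-area truth is the exact closed form);
  and three-branch capsule tubes whose branches leave a common joint at
  ≥100° separation — under that separation the union volume has the exact
  form $V = \tfrac{4}{3}\pi r^3 + \pi r^2 \sum L_i$, while the attached
  tube surface-area truth is a capsule-composition estimate and is
  labelled `composite`.
* **Volumes** are lognormal (median 0.25 µm³, sdlog 0.55 for adults,
  winsorized to [0.03, 4] µm³ for printability on the grid) — a long
  right tail is the realistic regime for BAT mitochondria. These defaults
  are stated stand-ins, not published values.
* **Aged effects are mechanistic, not cosmetic.** Aging multiplies the
  volume scale (×1.6) and dispersion (×1.5), multiplies the branched-tube
  *odds* (×2.5, which lowers sphericity and raises MCI through geometry),
  multiplies planted cristae density (×0.6), and shifts the cristae
  morphology mix toward fragmented "island" and annular "circular" forms.
  Because recovery tests run the full digitize→measure→compare path, a
  bug anywhere in the geometry stack breaks them.
* **Cristae planting** erodes the mitochondrion by one voxel (membrane
  clearance), then stacks slabs (lamellar), intersects an interior shell
  with the stacking (circular), or scatters small blobs (island), choosing
  the slab thickness/gap/phase that best matches the requested density;
  the realized density is recorded exactly from voxel counts and lands
  within 10% of the request for feasible geometries.
* **Scores** are linked to the pooled quantiles of realized cristae
  density (quartiles → scores 1–4), so the score effect co-varies with
  the density effect exactly as in the tissue data; three simulated
  blinded raters deviate ±1 level with probability 0.15 each side.

Everything is reproducible from a single seed: the truth table is drawn
first (`sample_cohort_truth()`), then digitized; measurement consumes no
randomness, so the streaming runner (`simulate_and_measure()`, which
builds and discards volumes ~25 objects at a time to bound memory) is
bit-identical to generating the whole cohort first.

What the phantoms do *not* emulate: EM texture and imaging noise,
segmentation error, true membrane physics of cristae, spatial clustering
of organelles, or inter-animal biological variation beyond sampling
variation. Passing recovery tests therefore demonstrates that the
*measurement and inference chain* is correct and directionally sensitive
at realistic effect sizes — not that the generator's parameter values are
the tissue's.

## Calibration experiments

Two standing experiments validate the statistical layer:

* **Parameter recovery** at study scale (seed-fixed): all five
  mitochondrial metrics significant in the planted direction (volume,
  surface area, perimeter, MCI up; sphericity down) and all three
  volume-normalized cristae metrics plus the mean score significantly
  down, at p < 0.05, object level.
* **Type-I calibration**: with every effect multiplier at 1.0, 200 seeded
  replicate comparisons of 50 objects per group must reject at a rate
  inside [0.03, 0.07] at α = 0.05. These replicates run on the
  generator's *pre-digitization* truth draws: the null concerns the test,
  and digitization adds only deterministic discretisation noise at ~100×
  the runtime, while the voxel path is already exercised by the recovery
  experiment.

## Degenerate inputs and tie-breaks

Empty volumes yield empty tables, not errors. Constant identical samples
compare as statistic 0, p = 1. Equal-volume bins that collapse quantile
edges raise an error advising fewer bins. Representative selection within
a volume bin takes the object nearest the bin median, ties to the lower
id. Cristae wholly in background stay unassigned (parent 0) and are
excluded from normalized comparisons. Density requests infeasible for a
tiny or thin mitochondrion raise an error; the cohort generator degrades
gracefully (lamellar fallback, then reduced density, then no cristae).

## Problem sizes used by the standing checks

The analytic oracle suite digitizes a 2 µm-radius sphere at full
anisotropic resolution (~6.7M foreground voxels) and a 1 µm cube at
isotropic 10 nm. Recovery runs the full 3 × 100 per group cohort;
type-I calibration uses 200 × 50-per-group truth-stage replicates;
determinism re-runs a 2 × 5-object pipeline twice and compares CSV bytes.

## Known limitations

* Surface areas of structures thinner than ~2 voxels fall back to raw
  meshing with a known positive bias; at 10 nm pixels this concerns only
  sub-20-nm laminae, which are at the resolution limit of the imaging
  modality itself.
* The slice-wise perimeter is one defensible operationalization among
  several; `sum` and `max` reducers are exposed for sensitivity analysis.
* Animal-level inference with 3 animals per group has little power; the
  package reports it as a caveat view, and deliberately implements no
  mixed model.
* Cristae sub-type classification (lamellar/tubular/circular/island) is a
  generator-side construct only; no decision rule is applied to measured
  data, because no quantitative criterion is established for one.
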
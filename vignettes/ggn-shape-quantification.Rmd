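---
title: "Quantifying ground-glass nodule shape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ground-glass nodule shape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggnshape)
```

## The measurement model

A persistent lung ground-glass nodule (GGN) seen on CT may be a precursor
glandular lesion (atypical adenomatous hyperplasia or adenocarcinoma in
situ), a minimally invasive adenocarcinoma, or an invasive adenocarcinoma
(IAC). Because management differs sharply between the first two groups
(PGL+MIA) and IAC, quantitative descriptors of nodule shape that separate
them are clinically useful. This package implements a chord-and-angle
construction on the nodule's maximal cross-section:

1. **Maximal cross-section.** Every slice of the segmented mask in the
   three orthogonal reformations (axial, coronal, sagittal) is scored by
   its foreground area (voxel count times the in-plane spacing product);
   the winning slice's boundary is the measurement substrate. Only the
   three orthogonal orientations are searched — no oblique planes — and a
   tie between planes resolves as axial > coronal > sagittal. **MA** is
   the shoelace area of that boundary (mm²).
2. **Longest diameter (LD).** The longest chord AB of the boundary,
   found by exhaustive search over all vertex pairs (a polygon's diameter
   is attained at vertices, so the search is exact at polygon level).
3. **Perpendicular diameter (PD).** The longest chord CD exactly
   perpendicular to AB that crosses it. Perpendicular lines are swept
   along AB (500 steps of LD/500 by default); at each foot the chord is
   the even–odd intersection of the line with the polygon. If a
   non-convex section yields several segments, the one straddling AB is
   used so that the intersection point O exists; with no straddling
   segment, the longest.
4. **Vertex angles.** A, B (the LD endpoints) and C, D (the PD
   endpoints) span a quadrilateral; the angle at A between rays A→C and
   A→D and the angle at B between B→C and B→D are reported in degrees.
   The larger is the big angle **BiA**, the smaller **SmA** — the LD
   endpoint closer to O always carries the larger angle, so the
   **BiA/SmA ratio** (≥ 1) measures how asymmetrically the mass sits
   about the chord intersection, while **LD/PD** (≥ 1) measures
   elongation. Angles at C and D are computed for completeness but enter
   no downstream statistic.

The construction assumes the segmentation is a single dominant region;
satellite components are dropped (largest boundary by area), and lesions
whose geometry degenerates (no closed boundary, no crossing perpendicular
chord) yield flagged records rather than failures, and are excluded from
cohort statistics.

## Numerical choices for raster inputs

A binary mask locates the boundary only to half a voxel, and the two
quantities this package cares most about — the PD foot and the LD endpoint
positions — are *flat optima*: near the width maximum the chord length
varies only quadratically with the foot, so half-voxel noise moves a raw
argmax by many voxels. Three stabilizations are applied, each exact in the
noise-free limit:

* **Slice pre-smoothing** (`sigma`, default 0.7 voxels). The binary slice
  is convolved with a small Gaussian before the 0.5-level marching-squares
  contour is taken. For a locally straight edge the smoothed indicator
  crosses 0.5 exactly on the true edge, giving sub-voxel vertices; the
  curvature-induced bias is about `sigma² κ / 2` ≈ 10⁻³ mm at CT-like
  resolutions. `sigma = 0` recovers the raw binary contour.
* **Boundary smoothing** (`boundary_smooth_mm`, default 0.5 mm for
  volumes, 0 for analytic polygons). A periodic moving average over the
  arc-length-uniform resampled boundary (360–2000 vertices) suppresses
  staircase wiggle; the inward bias is about `w²/(24 ρ)` ≈ 10⁻³ mm.
* **Chord stabilization.** The LD endpoints are refined to the centroid
  of the near-extreme boundary arc (chord length within 0.2% of the
  maximum), which is symmetric about the true tip for a locally quadratic
  tip profile. The PD foot is the apex of a piecewise-quadratic least
  squares fit to the *squared* width profile over the near-maximal region
  (width within 12% of the maximum): for elliptic flanks the squared
  width is exactly quadratic in the foot coordinate, so the fit recovers
  the true peak even with unequal flank curvatures, and pooling the whole
  region averages out raster aliasing. The reported PD is measured at the
  fitted foot.

With these defaults, 0.1 mm rasters of bi-ellipse phantoms across
rotations recover LD and PD within about 0.5%, LD/PD within 2%, and both
vertex angles within 2°; analytic polygons are recovered to ~10⁻³ degrees.
MA is always measured on the raw extracted boundary, before resampling or
smoothing.

Physical coordinates are voxel centres, `(index − 0.5) × spacing` mm, with
array axes ordered (x, y, z). All lengths are mm, areas mm², angles
degrees.

## The synthetic nodule family

Real GGN cross-sections have no closed-form chords, so validation uses a
**bi-ellipse**: a left half-ellipse with semi-axes (a₁, c) joined to a
right half-ellipse (a₂, c) on the shared minor axis, with a₁ ≥ a₂ ≥ c.
Every descriptor is then analytic:

* LD = a₁ + a₂ (the joined major axis), PD = 2c (the shared minor axis);
* angle at the far LD endpoint = 2·atan(c/a₁), at the near endpoint =
  2·atan(c/a₂), so BiA/SmA = atan(c/a₂)/atan(c/a₁);
* MA = π·c·(a₁ + a₂)/2.

```{r}
biellipse_truth(biellipse_params(6, 4, 3))
```

`params_from_targets()` inverts these forms (monotone 1-D root finding on
a₂), so cohorts can be generated to hit prescribed LD, LD/PD and BiA/SmA
distributions exactly; the feasibility bound BiA/SmA ≤
atan(1)/atan(c/(LD−c)) is reported when targets are unreachable.
`sample_cohort()` draws the two groups (default 39 PGL+MIA vs 59 IAC) from
truncated normal distributions with the reference cohort's means and SDs
(LD 11.818 ± 4.742 vs 19.488 ± 6.060 mm; LD/PD 1.247 ± 0.161 vs
1.491 ± 0.568; BiA/SmA 1.055 ± 0.042 vs 1.136 ± 0.080), truncated to
LD ∈ [3, 30] mm (nodules at most 3 cm) and ratios ≥ 1.001. Infeasible
triples are redrawn; if the estimated infeasible rate exceeds 10% the
sampler stops with advice. Shapes carry a random in-plane rotation and a
small radial boundary jitter (0.05 mm by default, a tracing-noise scale);
demographics (sex, age, lobe) follow the reference cohort's composition.

What the bi-ellipse deliberately does **not** model: spiculation,
lobulation, pleural indentation, non-convex outlines, solid cores, HU
texture, and any within-group correlation between LD and BiA/SmA (draws
are independent). Passing the recovery suites therefore demonstrates that
the *measurement machinery* is unbiased and stable on smooth convex
shapes at CT-like resolution — not that the clinical effect sizes
transfer to irregular real lesions. The absence of a known feature
correlation is also why the combined-model discrimination of the
reference study is not reproduced numerically: the combined AUC depends
on that correlation, which independent draws cannot supply.

## Cohort statistics

`compare_groups()` reports per-group mean ± SD with both Welch's t and
Mann–Whitney p-values (the reference analysis says only "t-test or
nonparametric test", so both are computed and the headline is
configurable; Welch is the default). Categorical baselines use Pearson's
chi-square without continuity correction — the variant that reproduces
the printed lobe-location p = 0.699; the printed sex p-value (0.527)
matches no standard chi-square variant (plain Pearson gives 0.539) and is
documented rather than chased. No multiplicity correction is applied,
matching the reference analysis.

`fit_logistic()` is a plain maximum-likelihood binary logistic regression
(IRLS, tolerance 1e-8, up to 100 iterations, no regularization) with Wald
odds-ratio CIs; quasi-separation is detected and flagged. The
**published model** `logit(P) = −34.571 + 28.443·(BiA/SmA) + 0.27·LD` is
kept as a first-class scorer: its per-mm LD odds ratio exp(0.27) = 1.310
matches the printed value, and its P = 0.5 level set is the printed
coefficient line.

`empirical_roc()` computes the ROC under the `score ≥ threshold` rule;
the AUC is the Mann–Whitney U statistic (ties count ½), which equals the
trapezoidal staircase area to machine precision, with a DeLong 95% CI
(the CI method is not stated in the reference; DeLong is the standard
choice and is cross-checked against pROC in the tests). The Youden
cut-off is the *observed score* maximizing sensitivity + specificity − 1,
smallest score on ties — matching the "ratio ≥ 1.068, LD ≥ 11.56 mm"
phrasing of the reference rule. Note the reference abstract reports a
different BiA/SmA cut-off (1.35) and LD sensitivity than its results
section; the results-section values are treated as canonical here.

## Problem sizes and reproducibility

The validation suites run at sizes chosen to make every oracle exact and
fast: exhaustive LD search is its own O(n²) oracle at ≤ 2000 vertices;
PD is checked against a 10× finer sweep; rasters use 0.1 mm phantoms;
statistical recovery uses n = 10,000 simulated lesions for the logistic
coefficients and 200 replicate cohorts of 39 + 59 for the AUC summaries.
Every stochastic step (cohort draws, jitter, rotations) is driven by a
single integer seed recorded in all written artifacts together with a
configuration hash, so identical configurations produce byte-identical
outputs.

## Known limitations

* Dual-reader consensus measurement is replaced by one deterministic
  computation; inter-reader variability is out of scope.
* PD endpoints are constrained to the extracted contour; whether the
  reference measurements allowed freehand endpoints is unknown, and this
  reading is recorded as such.
* Angle accuracy degrades below ~4 voxels across the minor axis (the
  generator warns); masks that coarse should be measured at finer
  reconstruction.
* The published equation is used as printed; refitting it on synthetic
  cohorts recovers coefficients of the generating model, not of the
  unavailable clinical cohort.
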
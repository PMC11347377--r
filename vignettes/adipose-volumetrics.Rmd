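---
title: "Adipose tissue volumetrics from PDFF maps: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adipose tissue volumetrics from PDFF maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

## What the pipeline computes

The package operates on pairs of co-registered 3D grids: a proton density
fat fraction (PDFF) map in percent and an integer label mask (0 background,
1 SAT, 2 VAT). PDFF is the fraction of MR-visible proton density in a voxel
attributable to fat; in adipose tissue it is high (around 90 % in
subcutaneous fat, slightly lower and more variable in visceral fat) but
never exactly 100 %, because adipocytes also contain water and MR-invisible
components. Three per-depot quantities follow directly:

* volume — voxel count × voxel volume, reported in liters;
* mean PDFF — the arithmetic mean over depot voxels;
* apparent lipid volume — Σ (PDFF/100) × voxel volume. "Apparent" because
  MR-invisible tissue components are not counted; it is always ≤ the depot
  volume, with equality only for a hypothetical pure-fat depot.

The craniocaudal **extent** of the segmented region is taken as the span
from the most superior to the most inferior slice containing *any* depot
voxel (SAT ∪ VAT), one shared extent per subject. Whether the original
anatomical protocol fixes the span by landmarks or by the segmentation
itself is not observable from the data we consume; the union rule is our
documented choice, and it matches segmentations that are themselves cropped
to the landmark range (liver dome to mid femoral head).

### Equidistant thirds

Regional distribution along the body axis is captured by splitting the
extent into three equal-length segments. Slices are atomic: each extent
slice is assigned to the third containing its physical center, with
boundaries at 1/3 and 2/3 of the extent. For `n` uniform slices the
comparison `3·(s + 0.5) ≥ n` (slice index `s` from the superior end) is
exact in floating point, so the partition is deterministic and every slice
lands in exactly one third — the thirds' volumes sum to the total *by
construction*, not approximately. An alternative would be to split voxels
across sub-slice boundaries; we deliberately avoid resampling, because the
conservation property is what downstream statistics rely on. With slice
counts not divisible by three the extra slice falls where the center rule
puts it (for example 91 slices give 30/31/30).

Normalized volumes divide by length: totals by the extent length, thirds by
their own length (≈ extent/3). Third-wise normalization is the only
convention under which a depot concentrated in one third shows a *higher*
normalized value there than the whole-region value, which is the comparison
the regional analysis needs.

### Change metrics

Changes between baseline and follow-up are signed: `follow − base` (so
losses are negative), and relative changes `100·(follow − base)/base` are
defined only for strictly positive baselines — empty-depot subjects are
excluded from the affected column with a logged count rather than imputed
as zero, since a zero would masquerade as "no change". Cohort-level
relative change is always the mean of per-subject percentages; on
heterogeneous cohorts this differs from the percentage change of the means
(a two-subject counterexample is unit-tested), and conflating the two is a
classic reporting error.

## The statistics layer

* **Paired / independent t-tests** via `stats::t.test`; the independent
  test defaults to the classic equal-variance form. Zero-variance inputs
  are flagged degenerate rather than producing NaN.
* **Standardized mean difference**: pooled-SD Cohen's d,
  `d = (m_after − m_before) / sqrt((sd_before² + sd_after²)/2)`, with a 95 %
  normal-theory CI using the paired-design standard error
  `SE = sqrt(2(1 − r)/n + d²/(2n))` where `r` is the before/after
  correlation. The paired SE matters: repeated measures on the same
  subjects are strongly correlated (r ≈ 0.9 for regional fat volumes), and
  an independent-groups SE would overstate the interval width several-fold.
  Published tables of this kind do not always state their CI formula; this
  choice reproduces the reported interval widths and is validated only to
  that degree. Magnitude labels use strict thresholds: |d| > 0.2 small,
  > 0.5 medium, > 0.8 large, so d = 0.5 is still "small" and d = −0.8
  "medium".
* **Correlation screening**: Pearson by default (Spearman available —
  method sections in this literature sometimes disagree between abstract
  and methods; we default to the one named in the methods and in the
  correlation tables we emulate). `screen_predictors()` ranks candidates by
  |r|, breaking ties by input order, and appends age and sex as mandatory
  covariates outside the top-k count.
* **Stepwise OLS** (`stepwise_ols()`): empty-start forward–backward
  selection. Each iteration admits the excluded candidate with the smallest
  partial t-test p-value if it is below `p_enter` (0.05), then removes the
  included term with the largest p-value if it is above `p_remove` (0.10).
  Whether such procedures start empty or full is often unstated; empty
  start is our documented choice and the entry/removal thresholds make the
  two converge in the regimes we simulate. `p_enter ≤ p_remove` is
  enforced (the reverse can cycle); an iteration cap plus repeated-state
  detection guards the loop; perfectly collinear candidates are skipped
  with a warning. The implementation is cross-checked in the test suite
  against an independently coded matrix-algebra stepwise on hundreds of
  random instances, and p-values are reported raw — the explorative designs
  we mirror apply no multiplicity correction, and neither do we.

Regression responses are modeled on the *fractional* relative-change scale
(percent / 100). Coefficient magnitudes like 0.24 per L/cm only make sense
on that scale, and the cohort generator plants its models there while the
tables carry both `d_*` (fraction) and `d_*_pct` (percent) columns.

## The synthetic-data generators

### Phantoms (`make_phantom`)

The phantom is an elliptic-cylinder torso: per slice, SAT is the annulus
between the outer ellipse (semi-axes 170 × 120 mm) and an inner ellipse
offset by the SAT thickness, and VAT is a concentric ellipse scaled so it
occupies a set fraction of the interior. Geometry is piecewise constant per
third, so every regional volume has an exact closed form (area × slice
thickness) and the only pipeline error is in-plane digitization — measured
at well under 1 % for study-scale depots on 3 × 3 × 6 mm voxels, against
the 2 % tolerance we test. Default profiles are calibrated to cohort-mean
values: SAT thickness (33.3, 45.6, 57.1) mm and VAT fraction (0.20, 0.67,
0.50) per third reproduce ≈ 15.5 L SAT rising toward the pelvis and ≈ 5.7 L
VAT peaking in the middle third over a 45 cm span (75 slices of 6 mm).
Voxelwise PDFF is drawn from clipped normals — SAT 90.39 ± 1.33 %, VAT
78.85 ± 4.10 %, background ≈ 3 % — which models measurement spread but not
spatial texture, bias fields, partial-volume mixing at depot boundaries, or
segmentation error. Passing the recovery tests therefore demonstrates
correctness of the volumetric arithmetic, not robustness to those real
artifacts, which are out of scope.

### Follow-up (`make_followup`)

An intervention is simulated by per-depot, per-third volume *retention*
fractions (defaults: SAT 0.787/0.808/0.781, VAT 0.866/0.760/0.765 — the
ratios of cohort-mean follow-up to baseline third volumes) plus a depot-wide
PDFF shift (SAT −1.96, VAT −4.18 percentage points). Shrinkage removes
voxels from the in-plane boundary inward: repeated 4-neighbour erosion
assigns every depot voxel a peel depth, and voxels are deleted in ascending
depth (ties by array order) until exactly `round(retention × n)` remain —
peripheral fat loss with the target met to a single voxel, deterministically.
Removed voxels are refilled with seeded background PDFF. Retentions so small
that a third would round to zero voxels raise an error naming the third.

### Cohorts (`make_cohort`)

Tabular cohorts draw baseline covariates from truncated normals (mean, SD
and physical range per variable, defaults matching an 81-subject, 49-female
study population), then generate the four relative-loss responses from
planted linear models. The default structure makes normalized lower-third
SAT volume (b = 0.24) and body fat % (b = 0.003) the drivers of fractional
SAT loss with target R² = 0.32, with analogous models for the other three
responses. Noise SD is calibrated against the *realized* signal variance,
`σ² = var(Xb)·(1 − R²)/R²`, so the mean realized R² across replicates sits
on the target (±0.05 is the tested band) while individual seeds fluctuate.
Covariates are drawn independently: the generator plants the reported
predictive relationships, not the full joint correlation structure of 30+
anthropometric variables, so tests of selection behavior on it speak to the
independent-predictor regime. With correlated real predictors, stepwise
selection is less stable than these simulations suggest — a known general
limitation of p-value stepwise procedures, which is precisely why the
implementation is held to oracle equivalence rather than to "finding the
truth" on every draw.

## Numerical and interface choices

* PDFF is carried in percent everywhere; lipid computations divide by 100.
* Volumes are liters (mm³ × 10⁻⁶), lengths centimeters (slices × slice
  spacing / 10).
* The craniocaudal axis is read from NIfTI orientation metadata ("S"/"I"
  letter of the xform); if the orientation does not resolve it, a
  configurable default axis is assumed with a warning. Flipping a volume
  along that axis (with the flag updated) swaps upper and lower thirds and
  changes no volume — an invariant under test.
* Empty depots return volume 0 but *undefined* (NA) mean PDFF and
  normalized values, with a condition-classed warning, so "absent" is
  distinguishable from "zero percent".
* Label codes are remappable at read time (`read_mask_nifti`); unknown
  codes are an error naming the file.
* CSV exports serialize doubles with 17 significant digits so written
  tables round-trip exactly.
* All generators take explicit seeds and restore the caller's RNG state;
  identical spec + seed gives bit-identical output.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use: one default-spec
phantom (128 × 96 × 80 voxels) per recovery check; 200 random extents (3 to
200 slices) for the thirds oracle; 500 random 81-subject cohorts with up to
7 candidates for stepwise-oracle equivalence; 500 planted-model replicates
for coefficient recovery; and 2000 null replicates for t-test calibration.
These sizes give Monte-Carlo standard errors comfortably below the
tolerances being asserted while keeping a full run in the low tens of
seconds.

## Known limitations

No MR physics (echo fitting, T2*, phase errors), no fat–water swaps, no
bias fields; no segmentation inference — masks are taken as given; no
registration between timepoints (subjects are summarized independently per
timepoint); two timepoints only, completers only; no multiplicity
correction by design. The sex covariate is an indicator (1 = female,
0 = male) drawn independently of the other covariates in the generator, so
sex-stratified analyses on synthetic cohorts exercise the code paths, not
sex-specific biology.
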
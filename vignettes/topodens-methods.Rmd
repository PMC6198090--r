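---
title: "Methods: topographic neuron-density mapping and micro-ROI statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topographic neuron-density mapping and micro-ROI statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topodens)
```

## The problem

Immunolabelling for plasticity markers (pMAPK, Arc, ...) marks the neurons a
behavioural episode activated, but classical counting reduces each section to
one number per region and discards *where* in the region those neurons sit.
`topodens` implements the opposite programme: keep every marker's (x, y)
coordinate in micrometres, register all subjects' sections into one frame
defined by a traced anatomical contour, discretise that frame into uniform
square bins, and treat the resulting subjects × bins count matrix as a
mass-univariate data set. Bins whose counts differ across experimental
conditions — after false-discovery-rate control — are *micro-regions of
interest* (MROIs): functional subdivisions finer than anything a brain atlas
delineates.

## Registration and units

All internal lengths are micrometres; Bregma planes are millimetres and are
converted only inside `sections_between()`. The registered frame follows the
image convention used when tracing on screen: the `(min x, min y)` corner of
the contour bounding box — the superior-left corner, with y increasing
ventrally — is translated to `(0, 0)`, and the identical rigid translation is
applied to all markers (`register_to_anchor()`). Whether the original screen
frame was y-up or y-down is not recoverable from coordinate files; the y-down
reading is a *convention*, stated once here, and all rendering labels the y
axis "ventral →" so maps read like the sections they came from.

Section-to-plane assignment is checked quantitatively rather than assumed:
the maximum Feret length of a nearby landmark (e.g. the caudate putamen,
which widens and lengthens rapidly along the rostrocaudal axis) is measured
per section, screened for outliers at ±3 sample SDs, compared *between*
planes with paired t-tests (planes should be distinct) and *across*
conditions with one-way ANOVA at each plane (conditions should not differ).
A non-significant condition ANOVA is reported as "no evidence of
misalignment", never as proof of alignment. Two caveats the package
documents and tests rather than hides:

* With the sample (n−1) SD, |z| is bounded by (n−1)/√n, so the ±3 SD rule
  **cannot** flag anything at n ≤ 10 sections per plane. `zscore_flag()`
  faithfully reports this as zero flags; users with small groups should
  lower the threshold knowingly.
* Flagged records are never dropped silently; exclusion requires the
  explicit `exclude_flagged` pipeline option.

## Bin size: the 2A/n rule

Bin area is `2 × A / n` — twice the sampling (contour) area per expected
item — so that under a uniform field each bin expects two items. `n`
defaults to the **mean** marker count per subject, which matches the
expected-frequency rationale of the rule; the source material elsewhere
describes `n` as a pooled total, so a `bin_n = "total"` switch exists and
the discrepancy is surfaced in the documentation. Bins are square
(`side = sqrt(2A/n)`): nothing in the method motivates anisotropy. Grid
extent defaults to the pooled min/max coordinate over all subjects (the
manual dialog's behaviour), each axis overridable; the final edge may
overhang the data and is flagged. Binning uses the half-open `[lo, hi)`
convention with the terminal edge closed — standard histogramming, no double
counting — and points outside the grid are counted and reported, never
dropped. Bins wholly outside the contour are retained in the matrix but
flagged, and are excluded from the multiple-testing family by default
(including them would dilute power arbitrarily).

## Maps

Per condition: the **mean map** (arithmetic per-bin mean across subjects),
the **SD map** (sample SD), and the **CV map** (SD/mean, a unitless
consistency measure). CV at mean 0 is *masked*, not set to 0 or ∞ — 0/0
carries no information. **Difference maps** subtract two mean maps on an
identical grid (no silent resampling; masks intersect). How subjects with
unequal totals should be weighted is genuinely open; raw counts are the
default and `normalize = "rate"` divides each subject by its total first.
Every rendered image is accompanied by a machine-readable sidecar table of
the exact per-bin values drawn, so the visual artefact is always testable.
Background photomicrographs are accepted as in-memory rasters with a
mandatory µm-per-pixel calibration (the pre-installed stack has no raster
*reader*, so file decoding is out of scope).

## MROI statistics

`mroi_detect()` runs one one-way ANOVA per bin across conditions (a
Kruskal–Wallis switch exists because rank tests are also used in this
literature), then Benjamini–Hochberg step-up FDR at q = 0.1. Choices worth
stating:

* Multiple section rows per subject are averaged first: no individual may
  appear twice in one test's sample.
* Counts are tested raw by default; a √-transform option exists and is a
  documented deviation. Low-count bins make the F test slightly
  conservative — acceptable, and quantified by the type-I simulations in
  the test suite.
* Bins with zero variance everywhere get p = 1 by convention and a flag.
* BH assumes independence/PRDS; neighbouring bins are spatially correlated,
  so a Benjamini–Yekutieli option is provided.
* Post-hoc `planned_contrasts()` (two-sample t or Mann–Whitney) are
  Bonferroni-corrected over every (contrast, bin) pair tested, restricted
  to the MROI set by default.

An FDR-controlled set is *expected* to contain ≈ q false discoveries among
its rejections, and those land anywhere on the grid. "The MROI set is
spatially contiguous around the hotspot" is therefore operationalised in the
tests as: the 8-connected component containing the hotspot-centre bin holds
at least 2/3 of all significant bins. Any all-bins-within-a-radius reading
would fail for a perfectly correct implementation.

`pca_topography()` decomposes the centred subject × bin matrix by SVD (well
posed with bins ≫ subjects; bins are centred, not scaled, since counts share
units). The *condition-separating component* is chosen by an explicit rule —
the component whose subject scores maximise the one-way F statistic against
condition — because the source material identifies its separating component
only descriptively. `mda()` solves the between/within generalized
eigenproblem for canonical variates of regional densities; reported loadings
are structure coefficients (pooled within-group predictor–score
correlations), and the predictor with the largest absolute loading on
variate 1 is reported as contributing most to the group difference.
`condition_anova()` gates per-region ANOVAs behind a Wilks' Λ MANOVA.

## The synthetic world

No histology data ship with the package; `scenario_effect()` /
`scenario_null()` generate a complete study with known ground truth, written
in the exact file dialects the readers parse:

* a 16-gon ≈ 600 × 450 µm elliptical contour (a dorsolateral-amygdala-scale
  ROI), registered;
* 7 + 7 subjects ("conditioned" vs "control") — group sizes of 5–7 are the
  realistic scale for this kind of experiment;
* per subject, an inhomogeneous Poisson process: ≈ 140 uniform background
  markers (rejection-sampled inside the polygon) plus, in the effect
  scenario's conditioned group only, Poisson(60) extra markers from a 2D
  Gaussian (SD 45 µm) truncated to the contour — truncation by redrawing,
  so the expected extra count *inside* the ROI is met exactly;
* a paired Feret table (three planes, means 2400/2550/2700 µm, subject
  noise SD 40 µm) exercising the QC path.

Everything is a pure function of (config, seed). What a green end-to-end
test establishes: under this stated world the pipeline recovers the planted
hotspot bin in ≥ 90% of 50 fixed seeds and returns an empty MROI set under
the matched null in ≥ 90%. What it does not establish: robustness to
contour-tracing variability between subjects, anisotropic or multi-modal
activation patterns, z-structure across sections, or label-intensity
artefacts — real data have all of these and the generator deliberately does
not.

Note the null-emptiness margin: under a global null, BH rejects with
probability ≈ q = 0.1, so ≈ 90% empty is the *theoretical* value and the
criterion sits exactly on it; the measured 92% clears it only because
discrete count data make the per-bin F test slightly conservative.

## Numerical and testing choices

* Boundary points count as inside the contour (no silent marker loss on
  traced edges); containment is crossing-number with a 10⁻⁹ µm boundary
  tolerance, validated against an independent winding-number oracle.
* Polygons are validated as simple (no self-intersection) with positive
  area at construction; the maximum Feret diameter is the exhaustive
  pairwise maximum over convex-hull vertices (hulls are tiny; rotating
  calipers would be over-engineering).
* `sections_between()` rounds to the nearest section and *flags* non-exact
  Bregma/thickness multiples instead of erroring — real cutting thickness
  varies.
* Sample (n−1) SD everywhere (QC z-scores, SD/CV maps): small-n histology
  groups.
* Monte-Carlo calibration tests use 3 MC SD bands: a 2 SD band falsely
  fails ≈ 5% of runs for an *exactly* calibrated statistic, and
  correctness is separately pinned by exact oracles (aov, t.test, cancor,
  exhaustive enumeration, brute-force loops).

## Limitations

Rigid translation is the only inter-subject registration — no rotation
fitting, no non-rigid warping; sections must already be reasonably aligned
by acquisition. One contour serves all subjects of a region/plane. Mixed
models / GEE / GAMM for bin-level repeated measures are out of scope, as is
3D (whole-brain clearing) analysis and kernel density estimation as an
alternative to binning.
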
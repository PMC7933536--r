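---
title: "Quantifying tumour-infiltrating lymphocytes: regions, measures and survival models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumour-infiltrating lymphocytes: regions, measures and survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilquant)
```

## The measurement problem

Tumour-infiltrating lymphocytes (TILs) are a candidate prognostic biomarker
for triple negative breast cancer, but published assessment protocols differ
in marker (pan-T CD3, cytotoxic CD8, regulatory FOXP3), in region
(intratumoural vs invasive margin vs stroma only), and in scoring method.
tilquant implements a common measurement vocabulary so that these choices
can be compared on equal footing: given a manually outlined tumour bulk, an
epithelium/stroma segmentation of the bulk, and per-marker lymphocyte point
detections — all routine outputs of a computational-pathology pipeline — it
computes cell densities in seven regions and relates each measure to
relapse-free survival (RFS) and overall survival (OS).

The package deliberately starts *after* image analysis: staining, spectral
unmixing, slide co-registration, cell detection and tissue segmentation are
upstream concerns whose outputs (polygons, label masks, points) are the
inputs here. The only geometric hook to upstream registration is an optional
2×3 affine transform applied to detections at load time.

## Coordinate and raster conventions

All coordinates are micrometres with the origin at the top-left and y
increasing downward — the native convention of slide scanners. Polygons are
lists of open rings filled by the even-odd rule, so necrotic holes in a bulk
outline are simply additional rings. Rasters use pixel-centre sampling with
0-based half-open pixel cells: pixel (i, j) owns
[x0+(j−1)·res, x0+j·res) × [y0+(i−1)·res, y0+i·res). These conventions are
stated once and used identically for rasterization, point assignment and
area accounting, which is what makes the conservation laws below exact
rather than approximate.

## Region construction

**Intratumoural regions.** ITA is the rasterized bulk. The compartment mask
labels every bulk pixel epithelium (ITT) or stroma (ITS); a segmenter that
emits a third class (e.g. fat) must have it merged by the caller, because
the intratumoural subdivision is defined as two-class. Since ITT and ITS
partition ITA on one pixel grid, `area(ITT) + area(ITS) = area(ITA)` holds
to machine precision and every detection inside the bulk is counted in
exactly one compartment.

**Invasive margins.** The bulk outline is dilated to both sides: the band of
half-width *w* is the set of points within Euclidean distance *w* of the
boundary, split into an inner (tumour-side) and outer half. With
*w* = 500 µm the effective margin is 1 mm (IM1); with *w* = 1 mm it is 2 mm
(IM2). We implement the dilation by thresholding an exact Euclidean distance
transform of the rasterized bulk (and of its complement), which is the
raster equivalent of a Minkowski sum with a disk — round joins, isotropic
width. The half-pixel offset between pixel-centre distances and the
pixel-interface boundary is subtracted, so a straight boundary at a grid
line yields band widths that are exact, and a brute-force
distance-to-outline oracle agrees with the band classification on ≥ 99.5%
of 5 µm grid points for random polygons (disagreements are confined to one
pixel of the band edge).

Three boundary cases are deliberate decisions rather than errors:

* a tumour thinner than 2*w* — the inner half then covers the whole bulk;
  the result is flagged (`inner_covers_bulk`), not rejected, because thin
  satellite foci are real;
* multi-focal tumours — bands are built on the shared raster, so overlapping
  bands of neighbouring foci are counted once;
* tumours abutting the section edge — the outer half is clipped to the
  tissue extent and the *clipped* area enters the density denominator,
  otherwise edge tumours would get artificially diluted outer densities.

## Measures

Densities are counts per mm² of region area. For regression they are scaled
per increment of 100 positive cells for CD3 and CD8 and per 10 for FOXP3,
whose absolute counts are an order of magnitude lower; without the rescaling
a FOXP3 hazard ratio per 100 cells would be an extrapolation far outside the
observed range. IM1IO/IM2IO are ratios of inner to outer half densities
— a crude spatial phenotype: ≈1 for an infiltrate indifferent to the
boundary, <1 for margin-restricted ("excluded") infiltrates. Between-marker
ratios (CD8/CD3, FOXP3/CD3, CD8/FOXP3) are computed from absolute counts in
the same region.

A ratio with a zero denominator is *undefined*, carried as `NA` — never 0 or
infinity — and the affected case is excluded from that measure's downstream
model with the exclusion counted and reported. No imputation rule would be
defensible, and degenerate measures should be visible as such, not papered
over; the survival table flags non-convergence rather than special-casing
it.

A point exactly on a region edge is assigned by a fixed tie rule: polygon
boundaries count as inside (the tumour side wins), and pixel-grid
boundaries assign to the pixel to the right/below, consistent with the
half-open cells. Any fixed rule preserves count conservation; this one is
the simplest to state.

Density heatmaps use a circle-shaped sliding window of area 1 mm² (radius
√(1/π) mm ≈ 564.19 µm); nodes whose window overhangs the frame divide by
the clipped window area. The 250 µm default stride is visualization
granularity only — no statistic is computed from the heatmap.

## Survival analysis

Each measure enters a univariable Cox proportional-hazards model as a
continuous covariate, for RFS and OS separately. Choices the package makes
explicit:

* **Ties:** Efron approximation — more accurate than Breslow when event
  times tie, and the cost is irrelevant at cohort scale.
* **Confidence intervals:** percentile bootstrap over patient resamples,
  5000 by default, seeded; resamples where the model is unfittable (no
  events, no covariate variation, diverging coefficient) are dropped and
  counted, and the interval is formed from the remainder.
* **p-values:** full-sample Wald test, paired with the bootstrap CI. The
  baseline alpha of 0.05 is *not* adjusted for multiple comparisons —
  the package's purpose is comparing assessment methods, not certifying any
  single one — but every significant result that would not survive a
  Bonferroni correction across the measures of the same marker and outcome
  is annotated (`bonferroni_robust = FALSE`).
* **Dichotomized view:** per measure, cases are split at the sample median
  (ties to the low group; standard interpolated median, so {1,2,3,4} splits
  at 2.5 and {1,2,2,5} at 2), Kaplan–Meier curves are computed per group and
  compared by the two-sample log-rank test. The log-rank implementation is
  cross-checked in the tests against a hand-tabulated O−E/V computation and
  against the Cox score test.

Degenerate inputs fail loudly where nothing sensible can be estimated (all
censored, fewer than two events, a constant covariate) and the survival
table records the failure per measure while the remaining measures proceed.

## The synthetic cohort: what it emulates, and what it does not

Because registry-linked imaging cohorts cannot be redistributed, the package
ships a generator that emulates the *statistical structure* the measures
assume, at a scale a laptop handles:

* **Geometry.** Bulk outlines are radial-Fourier perturbed disks
  r(θ) = R(1 + Σₖ aₖ cos(kθ + φₖ)), with R ~ N(1.5, 0.35) mm (truncated at
  0.6 mm) and Σ|aₖ| ≤ 0.35, which guarantees a star-shaped, simple polygon.
  Compartment masks are smooth Gaussian noise fields thresholded at the
  quantile that hits the target epithelium fraction (default 0.5) exactly;
  the blob scale (~frame/18) is in the few-hundred-µm range of real
  epithelial nests.
* **Infiltrates.** Per-marker inhomogeneous Poisson processes, sampled by
  thinning a homogeneous proposal at the per-pixel intensity. Default CD3
  intensities are 500 cells/mm² in tumour stroma, 150 in tumour epithelium
  and 250 in peritumoural tissue — stroma leads because that is where
  lymphocytes reside; CD8 is 0.4× and FOXP3 0.1× CD3, matching their
  relative abundance. A shared lognormal
  case factor (sdlog 0.6) and a small per-marker factor (sdlog 0.2) create
  the strong between-tumour heterogeneity that real cohorts show and that
  the survival models need as covariate variance. Three phenotypes span the
  behaviours the IM1IO/IM2IO ratios are designed to detect: *inflamed*
  (uniform per compartment), *excluded* (intratumoural intensity decays as
  exp(−d/τ), τ = 200 µm, with depth d), *desert* (no cells inside the bulk).
* **Masks at 10 µm/px.** Real compartment masks come from 0.12 µm/px scans;
  the generator works at 10 µm/px so a full case (geometry, regions,
  measures) takes ~0.2 s. The constant `HNE_SCAN_RESOLUTION_UM` records the
  native scale for real-data import.
* **Outcomes.** OS times follow a Weibull proportional-hazards model
  (shape 1.2, scale 90 months) with log-hazard log(0.85) per unit of the
  chosen covariate (default `CD3_ITA`, centred). Administrative censoring is
  uniform on (0, c_max) with c_max calibrated by root-finding so the
  realized censoring fraction hits the target (default 0.67, i.e. ~33% OS
  events). Recurrence is a latent event at a uniform fraction of the
  survival time, observed only when it precedes censoring — RFS events are
  a subset preceding OS events (~23% at the defaults) and
  `rfs_months ≤ os_months` by construction. Cohort size defaults to 94.

What the generator does **not** emulate — and therefore what green tests do
not certify about real data: segmentation noise in ITT/ITS (real
epithelium/stroma classifiers err on atypical TNBC morphology), detection
false positives/negatives, co-registration error beyond a global affine,
anisotropic or infiltrative growth patterns that break star-shapedness, and
informative censoring. The generator validates the measurement and inference
machinery, not any biological claim.

## Numerical choices and problem sizes

* Rasterization is even-odd scanline with pixel-centre sampling and
  half-open vertex handling; its oracle in the tests is an independent
  point-in-polygon routine.
* Distance thresholds compare `(distmap − 0.5) · res` against the half
  width, placing zero at the pixel interface.
* The heatmap's clipped window area uses trapezoid quadrature with 400
  slices; the error is far below the Poisson noise of any window count.
* Bootstrap quantiles are type-7; seeds are localized so library calls do
  not perturb the caller's RNG stream, and per-model seeds are derived from
  the master seed so partial re-runs are stable.
* Report percentages round half-up to one decimal (the convention of
  clinical tables), not banker's rounding.

The test suite sizes its simulations to finish in minutes on one core while
keeping Monte-Carlo error well inside the asserted tolerances: 100 cases for
conservation laws, 200 for the inner/outer homogeneity property (means
within 3 SE of 1), 50 cohorts of n = 300 with 500 bootstraps for hazard
ratio recovery and CI coverage, 1000 null replicates of n = 150 for the size
of the Wald test, and a closed-form two-group exponential check at
n = 80 000 where sampling error is ~1%. The analysis default remains 5000
bootstraps.

## Limitations

* Regions are raster-based; at a user-chosen resolution coarser than the
  annotation detail, band areas inherit pixel quantization (one-pixel
  tolerance in the conservation checks). Work at 1–5 µm/px for real slides.
* The Cox models are univariable by design — the point is comparing
  measures, not building a multivariable prognostic model; no
  proportional-hazards diagnostics or competing-risks handling is included.
* Marker-pair ratio measures are frequently degenerate in practice (zero
  denominators, tiny variance); the package reports whatever the model
  yields with convergence flags rather than suppressing them.
* The CLI (`inst/cli/tilquant.R`) is a thin wrapper; programmatic use via
  `run_pipeline()` is the primary interface.
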
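---
title: "Methods: cytological profiling, confidence-ellipse concordance, and the supporting assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytological profiling, confidence-ellipse concordance, and the supporting assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcprofiler)
```

## The problem

Bacterial cytological profiling (BCP) infers an antibiotic's mechanism of
action (MoA) from the morphological and fluorescence changes it induces in
single cells. Cells treated with a query compound and with a panel of
reference antibiotics of known MoA are imaged in several fluorescence
channels (a membrane stain, a DNA stain, and a membrane-permeability
stain), tens of cytological parameters are measured per cell, and the
query is assigned the MoA of the reference whose per-cell profile
distribution it most resembles. `bcprofiler` implements one complete,
testable version of this chain, from micrograph (or synthetic stand-in)
to a ranked table of references.

## The concordance statistic

For each (query, reference) pair the package:

1. subsamples both treatments to a common cell count `n` (by default the
   smaller of the two), so each treatment carries equal weight;
2. pools the two treatments' cells, centres and scales every parameter on
   the pooled data, and computes a PCA (`stats::prcomp`). Pooled
   standardization is what makes the two treatments live in a single
   comparable PC space — a per-treatment standardization would erase
   exactly the differences the method is after;
3. fits a confidence ellipse to each treatment's PC1–PC2 scores;
4. computes, over the union of all cells of both treatments,

   $$\mathrm{concordance} \;=\;
     \frac{\#\{\text{cells inside both ellipses}\}}
          {\#\{\text{cells inside either ellipse}\}} \in [0, 1].$$

The statistic is a Jaccard-type overlap of the two treatments' 95%
regions, evaluated on the observed cells rather than on area. It is
symmetric, invariant to affine rescaling of any parameter (absorbed by
standardization) and to the order of parameter columns; both invariances
are property-tested. References are ranked by descending concordance
(`rank_references()`), and the top ranks are read as MoA neighbours.

### Confidence ellipses

An ellipse is parameterized by its centre (the score mean), a 2×2 shape
matrix (the sample covariance of the scores) and a squared Mahalanobis
radius. Two radii are offered:

* `method = "t"` (default): $r^2 = \frac{2(n-1)}{n-2} F_{0.95}(2,\,n-2)$,
  the small-sample construction common in plotting software;
* `method = "normal"`: $r^2 = \chi^2_{0.95}(2)$, the large-sample
  Gaussian ellipse, whose coverage on its own points converges to the
  nominal level (tested at $n = 10^4$: 95% ± 1%).

The two agree as $n \to \infty$. Membership is decided exactly by the
quadratic form $(x-c)^\top S^{-1}(x-c) \le r^2$, never by rasterization;
equivalence with a brute-force rasterized test is asserted on small
instances. Which estimator the original BCP analyses used is generally
not reported; both are exposed, and the default is documented rather than
silently assumed.

### What standardized PCA can and cannot see

Because parameters are scaled to unit pooled variance, a treatment effect
confined to a *single* parameter inflates that parameter's variance but
induces no cross-correlation: the pooled correlation matrix stays near
the identity and PC1 has no reason to align with the affected parameter.
Effects spanning two or more parameters induce pooled correlations that
PC1 does pick up. The test suite encodes this distinction explicitly; it
is a property of correlation PCA, not of this implementation.

## Quality control

Three filters run in a fixed order, each only deleting rows:

1. **Missing-data removal** — any cell with at least one missing
   parameter is dropped.
2. **Within-treatment 5-SD outlier removal** — per treatment, each
   parameter's mean and sample SD (denominator $n-1$) are computed once,
   and any cell beyond $k$ SD (default $k = 5$) in any parameter is
   dropped. The pass is deliberately single: statistics come from the
   pre-removal table, so the filter is *not* idempotent (removing a gross
   outlier shrinks the SD; a second application could remove more — the
   suite demonstrates this on a constructed example). Zero-SD parameters
   never remove cells, which keeps the rule deterministic on degenerate
   data. On clean multivariate-normal data the filter removes essentially
   nothing ($P(|z|>5) \approx 5.7\times10^{-7}$ per entry; asserted < 1%
   at $n = 10^4$ cells × 39 parameters).
3. **Balanced subsampling** — uniform without replacement to a common
   per-treatment count, by default the minimum across treatments
   (217 in a typical real panel, where the least-populated treatment had
   217 cells; the number is a property of the data, not of the method).

Whether the original analyses used population or sample SD, or stratified
the subsample by replicate, is typically unreported; sample SD and
unstratified sampling are this package's documented choices. Replicates
are carried as labels only — the PCA pools cells across replicates.

## The imaging front end

Cells are segmented on the membrane channel: Otsu threshold, 8-connected
components (EBImage's 4-connected labelling plus a diagonal merge),
optional phase-guided expansion (up to `expansion_px` one-pixel rings,
accepting pixels whose phase intensity is within 3 SD of the object's
interior statistics), and removal of border-touching objects — truncated
cells would corrupt every shape feature, so they are excluded outright.
Nucleoids are connected components of the DNA channel, associated to the
cell whose mask contains their centroid; cells without an associated
nucleoid are excluded (the DNA-presence gate used to reject debris and
ghost cells).

The default feature registry emits **39 parameters**: 12 shape
descriptors (area, perimeter, moment-equivalent spherocylinder length and
width, eccentricity, orientation, solidity, form factor, compactness,
extent, max/min Feret diameters) and 9 intensity statistics (mean,
median, SD, min, max, integrated, lower/upper quartile, mass
displacement) on each of the three fluorescence channels. The registry is
a configurable reconstruction of a CellProfiler-style measurement set;
the *count* is the contract, the identity list is configurable. Intensity
statistics are refused on channels flagged as deconvolved — quantitative
fluorescence must come from raw data.

Axis lengths deserve a note: the usual ellipse-moment convention
(`4*sqrt(eigenvalue)`) overestimates the width of a rod by ~20%, because
a capsule's cross-section is uniform, not elliptical. The package instead
inverts the capsule's own second-moment equations (a monotone 1-D root
solve in the aspect ratio), which recovers a rod's true length and width
and degrades gracefully to the equivalent-disk diameter for round
objects.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, seeded, tested code:

* `gen_feature_table()` draws each treatment's cells from a multivariate
  normal with treatment-specific mean and covariance, assigns four
  replicates round-robin, and contaminates entries completely at random
  (missingness) and cells with single-parameter gross displacements
  (outliers — exactly one parameter per contaminated cell, which makes
  the 5-SD filter's action exactly predictable in tests). Defaults follow
  the realistic panel scale: ≥ 217 cells per treatment, 39 parameters,
  four replicates.
* `gen_image_scene()` renders capsules (spherocylinders — the idealized
  rod-shaped *B. subtilis* footprint) of uniform per-channel intensity on
  a constant background with optional Gaussian noise, single focal plane,
  no point-spread function and no deconvolution. Nucleoids are rendered
  as a centred sub-capsule (60% linear scale) in the DNA channel, only
  for cells flagged as having one. Pixels are 0-based (row, col), origin
  top-left; geometry is evaluated at pixel centres with a 1e-9 tolerance
  on the boundary so rotated cells rasterize stably.
* `gen_plate()` and `gen_dose_response()` produce step-OD microdilution
  plates (blank OD at and above the true MIC) and 4PL viability curves.

The Gaussian mean-shift model is a stand-in: real cytological profiles
are skewed, heteroscedastic and replicate-structured, and real treatment
effects are not mean shifts alone. Passing tests on synthetic panels
therefore demonstrate that the statistics are implemented correctly and
behave as designed under a known model — not that the method's biological
error rates on real micrographs are any particular value.

## Assays

* `cfu_per_ml(df, colonies, vol)` = df × colonies / vol.
* `read_mic()` quantifies "no visible growth" as OD ≤ blank + margin
  (default margin 0.05 OD — a numeric proxy for a visual call), and
  reports the MIC only at the plate's discrete twofold steps. Censored
  plates return `"> max"` / `"<= min"`; non-monotone plates (growth above
  a no-growth well) are flagged and called above the highest growth well.
* `fit_4pl()` fits $v(c) = b + (t - b)/(1 + (c/\mathrm{IC}_{50})^{h})$
  by Levenberg–Marquardt least squares on the log-concentration scale
  from a fixed multi-start grid (5 log-IC50 quantiles × 6 Hill slopes),
  keeping the lowest residual sum of squares — deterministic given the
  data. The Hill slope is unconstrained in sign, so rising and falling
  curves both fit. Flat data are refused (IC50 unidentifiable).

The simulation conditions used in the recovery tests are a steep sigmoid
(IC50 50 µM, Hill 2 — steep slopes are typical of membrane-permeabilizing
compounds), a 12-point twofold series from 1000 µM down (spanning both
plateaus, as the fitting precondition requires), and 5-percentage-point
Gaussian noise; under these, the median relative IC50 error over 50 seeds
is comfortably below 10%. When the series fails to reach the lower
plateau the error of *any* least-squares fit roughly doubles — a design
property worth knowing before trusting an IC50 from a truncated curve.

## Formula arithmetic

`monoisotopic_mass()` sums most-abundant-isotope masses from an embedded
NIST/CODATA table (≥ 6 dp; no lookups at run time). `mz_deprotonated()`
subtracts one hydrogen atom and adds one electron mass — the electron
correction matters at the fourth decimal place: for C~15~H~28~O~2~ the
deprotonated ion computes to 239.2017, where neglecting the electron
would give 239.2011. `degree_of_unsaturation()` uses
$(2C + 2 + N - H - X)/2$ with halogens counted as hydrogen and O/S
ignored; for C~15~H~28~O~2~ it is 2 (one C=O + one C=C — a
monounsaturated fatty acid).

## Problem sizes and numerical choices

The test suite validates the statistics at the sizes where their
guarantees are sharp but cheap: ellipse coverage at 10^4^ points,
concordance against a 10^5^-point analytic Monte-Carlo oracle at group
sizes of 5000, QC behaviour at 10^4^ cells × 39 parameters, MoA recovery
on panels of 250 cells × 39 parameters × 6 references over 20 seeds, and
4PL recovery over 50 seeds. All randomness flows through explicit seed
arguments; generators save and restore the session RNG state. Ties on an
ellipse boundary are included (≤); ties on a capsule boundary are
included with a 1e-9 tolerance; the PCA loading sign is fixed by making
each column's largest-magnitude entry positive.

## Known limitations

* The phase-guided expansion rule (interior mean ± 3 SD) is a plausible
  reconstruction; the original CellProfiler operator is not public.
* Segmentation is validated on non-overlapping synthetic capsules;
  touching cells are not split (no watershed), matching the fixtures'
  scope, not real dense fields.
* The registry's 39 defaults reconstruct a measurement set whose exact
  identity is not published; analyses that depend on a specific
  parameter's meaning should configure the registry explicitly.
* Concordance compares PC1–PC2 only, by construction; structure in
  higher components is invisible to it.
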
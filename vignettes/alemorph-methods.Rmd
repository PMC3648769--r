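---
title: "Models, parameters, and design choices in alemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters, and design choices in alemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alemorph)
```

This vignette is the package's own account of the science it implements:
the two inference models and their assumptions, the parameters that matter
and why their defaults are what they are, what the synthetic-data
generators do and do not emulate, the numerical conventions, and the design
choices made where the underlying procedures are genuinely underspecified.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The ALE model

Coordinate-based meta-analysis works from published activation peaks
("foci"), not from image data. Each focus is treated as the center of a
spatial probability kernel — an isotropic trivariate Gaussian with
full-width at half-maximum `fwhm_mm`, so `sigma = fwhm / (2 sqrt(2 ln 2))`.
The probability a focus contributes at a voxel displaced by `d` is

```
p = min(1, w * phi3(d; sigma) * V)
```

with `V` the voxel volume and `w` the focus weight. Per-voxel evidence
combines by the probabilistic union `1 - prod(1 - p)`, first over the foci
of one study (the modeled-activation map), then over studies (the ALE map).
Because `1 - MA_s = prod_i (1 - p_si)`, the two-level union algebraically
equals a single product over all foci; the package exploits this in the
permutation loop but keeps the two-level structure in `ale_map()` because
the per-study normalization is defined at the study level.

**Per-study normalization.** Every focus of a study carries weight
`1 / n_foci(study)`, so each study contributes total kernel mass 1 and a
study reporting many peaks cannot dominate the map. The phrase "the summed
ALE of all peaks of each study was normalized to unity" admits a second
reading — rescaling the finished study map so its voxel sum is 1 — which
this package deliberately does **not** implement; the per-focus-weight
reading is the most direct one and keeps probabilities interpretable.
A consequence worth knowing: splitting or duplicating foci *within* a study
leaves that study's total mass unchanged, so the permutation null's mean is
essentially flat in per-study focus counts and grows with the number of
studies. (One of the inference tests pins this down.)

**Assumptions.** Foci are exchangeable within a study; kernels are
isotropic and identical across studies (no subject-count-dependent widths);
the mask defines both the analysis region and the null's spatial support.

### Inference: the single-threshold permutation test

The null hypothesis is spatial randomness of foci within the mask. Each
permutation redraws every study's observed number of foci independently and
uniformly over mask voxel centers (with replacement), recomputes the ALE
map on the mask, and pools **all** in-mask voxel values across
permutations. The critical score at level `alpha` is the inclusive
empirical quantile — the `ceiling((1 - alpha) * N)`-th order statistic —
and observed voxels survive iff their ALE value is **strictly** greater.

Two open points were settled as follows:

- *Pooled-voxel null vs per-permutation maxima.* The pooled (uncorrected,
  single-threshold) variant is implemented, matching the original form of
  the test this procedure descends from. A max-statistic null would give
  family-wise control and a higher critical score; it is out of scope.
- *Null placement on voxel centers* rather than continuously in the mask
  interior: unambiguous, and consistent with evaluating maps at voxel
  centers.

Calibration is testable: with the critical score built at `alpha`, fresh
null maps from the same generator exceed it at a per-voxel rate of `alpha`
within Monte-Carlo error. The acceptance suite exercises this at
`alpha = 0.01` with a ~580-voxel toy mask, 10 studies of 5 foci, a
1,000-permutation null, and 200 fresh maps.

## 2. The VBM correlation stage

The pipeline starts from spatially aligned gray-matter density volumes
(segmentation and nonlinear template registration are upstream, out of
scope) and a per-subject behavioral score.

1. **Smoothing**: separable Gaussian filtering specified in mm
   (per-axis sigma derived from the voxel size, so anisotropic voxels are
   handled); `fwhm = 0` is the identity. The default 6 mm matches common
   practice for density images.
2. **Model**: per voxel, `intensity ~ intercept + score`;
   `T = slope / SE(slope)`, `df = n - 2`, identical to the Pearson identity
   `T = r sqrt((n-2) / (1-r^2))`. P-values are **one-sided upper tail**: the
   target effect is a positive structure–score association, mirroring a
   one-sided T contrast. No nuisance covariates (age, total GM) — the
   modeled analysis is a simple correlation; extending the design matrix is
   a non-goal.
3. **Thresholding**: binarize at `p < p_voxel` (default 0.001,
   uncorrected), label connected components (default 18-connectivity, the
   common default of the software family this mirrors; 6 and 26 are
   configurable), and keep components **strictly larger** than `k_min`
   voxels (default 150, i.e. "more than 150 contiguous voxels"). Note the
   source material for this rule is internally inconsistent — a figure
   caption says `k > 1.0` where the methods text says `k > 150`; the
   methods value is the default here.
4. **Peaks**: within a cluster, voxels are ranked by descending T (ties
   broken by lexicographic voxel index) and greedily accepted subject to a
   minimum mutual separation (default 8 mm). Deterministic by
   construction; the underlying procedure states no peak rule.
5. **ROI overlap**: a sphere ROI (center and radius are *user inputs* — the
   canonical "domain-general region" center is not part of the package's
   data) is rasterized by voxel-center inclusion and intersected with the
   cluster map.

## 3. Coordinate conversion

Talairach-labeled foci are converted to MNI by inverting the standard
piecewise-affine mapping: rotation about x by 0.05 rad composed with axis
scalings `diag(0.99, 0.97, 0.92)` above the AC plane and
`diag(0.99, 0.97, 0.84)` below it. The branch is decided by the sign of the
**Talairach-side** z in both directions (for MNI→TAL this is the rotated
z, whose sign equals the output z because the scalings are positive). The
historical script branches MNI→TAL on the raw input z; the two conventions
differ only for points with large |y| very close to the AC plane, and the
convention chosen here makes the pair an exact inverse everywhere — a
property the test suite asserts on a ±70 mm lattice. Minor variants of
these matrices circulate; the matrices above are this package's contract.

## 4. The questionnaire module

The 25-item scale has 22 positively and 3 negatively worded items on a 1–7
Likert range; totals are sums with negative items reverse-coded as
`r -> 8 - r` (the standard Likert reversal; the instrument's description
implies reversal but prints no formula). Totals lie in [25, 175].
*Which* three items are negative, and the 13/12 split into fictitious vs
real-life situations, are not published — the default `escale_key()` is an
explicitly synthetic stand-in satisfying the published counts, and a real
key can be supplied as a CSV.

Normality is checked with a one-sample Kolmogorov–Smirnov test against the
normal fitted to the sample (its own mean and SD), with the asymptotic
Kolmogorov p-value. Because the reference parameters are estimated from
the same data, this p is anti-conservative (the Lilliefors caveat); it is
computed this way because that is what the common statistics packages this
mirrors do by default. `ks_normality()` accepts explicit reference
parameters when a proper fixed-reference test is wanted.

## 5. The synthetic world

The generators produce every input the pipeline consumes, with the
statistical structure the analyses assume — and nothing more.

- **Foci tables** (`simulate_foci`): per study, `Poisson(lambda) + 1` foci
  (default lambda 2, ~3 foci/study, in the range of real coordinate
  tables); each focus is a mixture of Gaussian scatter (default sigma 4 mm)
  around latent centers and uniform background over mask voxels (default
  10%), exercising both the in-mask and the 5-mm-tolerance branches of the
  outlier filter. A configurable fraction of rows (default 30%) is stored
  in Talairach coordinates by *forward* conversion, so harmonization must
  recover the recorded MNI ground truth exactly.
- **Cohorts** (`simulate_cohort`): latent totals from
  Normal(91.6, 13.3) truncated to [25, 175] (the published cohort's
  summary; truncation is negligible at these values), rounded and
  decomposed deterministically into 25 valid item responses that re-score
  to the drawn total exactly. Item-level structure is *valid, not
  psychometrically realistic* — the pipeline only consumes totals.
- **Gray matter** (`simulate_gm_dataset`): constant baseline 0.5 plus
  `beta * (score - mean(score))` times a parabolic spherical bump
  `max(0, 1 - (d/r)^2)` plus i.i.d. Gaussian noise, then smoothed. The
  parabolic profile makes the true effect peak at the locus, so peak
  recovery is well defined. Defaults — 24³ voxels at 2 mm, radius 10 mm,
  `beta = 3e-3` intensity units per score unit, noise SD 0.05, 6-mm
  smoothing — were fixed a priori by a power calculation (center
  T ≈ `beta * sd(score) / noise_sd * sqrt(n)` ≈ 8 before smoothing for
  n = 101, score SD 13.3; smoothing raises it further) and then verified by
  the recovery criterion, not tuned to it.

What the generators do **not** emulate: brain-shaped anatomy or tissue
boundaries, spatially correlated physiological noise, registration error,
inter-study heterogeneity beyond the stated mixture, or item-response
psychometrics. A green recovery test therefore establishes that the
statistics chain is correct and well calibrated on its own assumptions —
not that the pipeline is robust to real-data violations of them.

## 6. Numerical conventions

- World coordinates in mm, RAS orientation; voxel indices 0-based;
  world→voxel rounding is half-away-from-zero (deterministic, symmetric
  about voxel centers).
- "Within 5 mm of the border" is operationalized as Euclidean distance ≤ 5
  mm (boundary inclusive) to the nearest foreground voxel *center* — 0 for
  interior points; mesh-free and exactly testable against a brute-force
  scan. Enlarging the tolerance can only grow the kept set.
- Union products are accumulated as `sum(log1p(-p))` and inverted with
  `expm1` for stability at small p; the per-voxel regression uses the
  *centered* sum of squares (the uncentered shortcut loses ~8 digits to
  cancellation when a constant baseline dominates) and flags zero-variance
  voxels as T = 0, p = 1 rather than erroring; exact fits (zero residual)
  give T = ±Inf.
- Smoothing uses a row-renormalized truncated kernel (half-width 4 sigma),
  so constants pass through unchanged at the image boundary and no
  spurious edge gradients appear in small synthetic grids.
- The empirical quantile is the inclusive order statistic
  `ceiling((1 - alpha) * N)`; ALE thresholding is strict (`>`), cluster
  extent is strict (`> k_min`), mask tolerance is inclusive (`<= tol`).
- All generators draw from a private RNG stream (`seed` argument) and
  restore the caller's `.Random.seed`; identical inputs and seed give
  bit-identical outputs.

## 7. Known limitations

- Kernel width is a free parameter (default FWHM 10 mm, the classic choice
  for this method family); the modeled analysis does not state its value,
  so quantitative ALE scores are comparable only within a fixed kernel.
- The pooled-voxel null provides per-voxel (uncorrected) calibration only;
  no family-wise or FDR control for ALE, and no cluster-level inference
  for it either.
- The VBM stage's p < 0.001 / k > 150 combination is a descriptive
  convention, not a corrected error rate.
- NIfTI support is deliberately minimal: uncompressed single-file `.nii`,
  3-D scalar images, common numeric datatypes, sform/qform affines. It is
  sufficient for the pipeline's own artifacts and for images written by
  mainstream tools under those constraints, and rejects what it cannot
  parse rather than guessing.
- The Talairach↔MNI mapping is a fixed piecewise-affine contract; no
  nonlinear registration, and no per-subject spatial normalization
  anywhere in the package.
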
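---
title: "Shell-based tumor volumetrics and pCR prediction: methods and design notes"
author: "pcrvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell-based tumor volumetrics and pCR prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrvol)
```

## The problem

Locally advanced rectal cancer is treated with preoperative concurrent
chemoradiotherapy followed by total mesorectal excision. Roughly a
quarter of patients show a pathological complete response (pCR, no
viable tumor in the resected specimen, operationalized here as rectal
cancer regression grade 1); identifying them *before* surgery would
support organ-preserving "watch and wait" strategies. `pcrvol`
implements a pretreatment prediction workflow built entirely on
volumetric imaging parameters derived from two delineated structures on
planning CT: the approximate tumor volume (ATV, the outer tumor contour
including the enclosed bowel lumen) and the intestinal tube cavity (ITC,
the lumen at the tumor level).

## The volumetric parameters

From a pair of binary masks with physical voxel spacing the package
computes nine parameters:

* **ATV**, **ITC**: member voxel count times voxel volume (cm^3^).
* **RTV** = ATV − ITC, the real tumor volume.
* **TSAO**: the volume of the outermost 1 mm layer of the tumor,
  obtained by a three-dimensional 1 mm contraction of the ATV and
  subtracting; **TSAI**: the 1 mm layer gained by enlarging the ITC;
  **TSA** = TSAO + TSAI. These shell volumes serve as surface-area
  surrogates and are reported on the shell-volume scale (a true area
  estimate, TSA divided by the 0.1 cm thickness, is exposed as
  `true_surface_cm2`).
* **TC** = RTV / TSA^1.5^, the tumor compactness score. Higher values
  mean a more compact (rounder, smoother) tumor; the clinical finding
  the package reproduces is that compact tumors respond better.
* **TML**: longitudinal extent, (last − first occupied slice + 1) ×
  slice spacing; **TMD**: the maximum in-plane Feret diameter over
  axial slices.

The shell-volume convention matters: the downstream stratum boundaries
and the published regression coefficients are calibrated to shell
volumes (numerically cm^3^), not to true areas. `TC = RTV/TSA^1.5` with
this convention equals the dimensionless isoperimetric-type ratio
`V/S^1.5` times the constant `0.1^-1.5`, so it is scale-invariant up to
curvature terms of order (thickness / feature size).

## Morphology in physical millimetres

Clinical CT slices (3 mm here) are thicker than the 1 mm margin, so
structuring-element morphology in voxel units cannot express an
isotropic 1 mm operation. `contractMask()`/`expandMask()` therefore
work with Euclidean center-to-center distances in physical mm — the
Euclidean-distance-transform convention: a voxel survives contraction
by *d* iff no in-grid complement voxel center lies within *d* of its
center, and expansion adds every complement voxel within *d* of a
member center. This is exact with respect to its definition (the test
suite checks it against an all-pairs brute-force scan, including
anisotropic spacings) and preserves the algebraic identities the
feature set relies on (nesting, monotonicity, conservation of volume
between a mask, its contraction and its shell).

Two numerical consequences are documented rather than hidden:

* **Quantization.** At 3 mm slice spacing a 1 mm operation acts only
  in-plane (no offset along the slice axis has physical length ≤ 1 mm).
  This mirrors what any voxel-based implementation at clinical
  resolution does, and it shifts the TSAO/TSAI scale relative to a
  contour-based planning system; the synthetic cohorts inherit this
  consistently, so strata and models remain internally coherent.
* **O(h) shell bias.** On a grid of spacing *h* the effective contracted
  margin is below *d* by a fraction of *h* (the nearest complement
  *center* overstates the distance to the complement *region*), so
  shell volumes underestimate their continuous closed forms; on a 20 mm
  sphere the deficit is ≈16% at *h* = 1 mm and ≈5% at *h* = 0.3 mm. The
  geometry oracle tests therefore compare shells to closed forms on
  0.3–0.4 mm grids, where the stated 2–5% tolerances hold honestly; no
  sub-voxel rule at *h* = 1 mm can do better (the achievable erosion
  sets jump from the 6-neighborhood, −16%, to the 18-neighborhood,
  +27%). The derived true-area estimate additionally carries the
  curvature bias ≈ t/r of the hollow-shell closed form itself; both
  biases are negative and are asserted as such in the tests.

Expansion never silently clips: an expansion that would leave the grid
raises an error, and the phantom generators size their grids with
margin.

## Ordinal coding

All fifteen predictors enter the models as ordinal stratum codes with
right-closed intervals ("> a and ≤ b"); the first bin is closed at its
upper bound. Age strata are decades repaired to contiguous intervals
(≤40, (40,50], (50,60], (60,70], >70) so fractional ages are always
codable; CEA is dichotomized at the 5 ng/ml clinical reference; CD44v6
immunohistochemistry collapses to low ('−', '+') versus high ('++',
'+++') expression. Coding is total on the non-negative reals, monotone,
and pure; property tests enforce all three.

## Regression pipeline

The analysis follows the standard screening workflow:

1. **Spearman correlations** among the volumetric parameters
   (tie-corrected, two-sided t-approximation p-values).
2. **Univariate logistic screening**: outcome on each coded factor
   alone; per-stratum odds ratio `exp(slope)` with Wald 95% CI.
   Complete separation is flagged, not silently returned.
3. **Collinearity screen**: VIF_j = 1/(1 − R²_j) from regressing factor
   *j* on the others, excluding the worst factor at VIF ≥ 10 and
   re-screening until all pass. The diagnostics run on
   measurement-scale values (ordinal clinical codes plus raw volumetric
   features): ATV and RTV differ only by the narrow lumen volume and
   correlate near 0.998 on the raw scale, which is exactly the
   near-duplicate the screen exists to remove — after five-level
   binning that dependence is masked (VIF saturates near 8), so a
   code-scale screen would never fire. TSA = TSAO + TSAI is an exact
   linear dependence and is likewise caught. Excluded features are then
   dropped from the coded design.
4. **Forward stepwise logistic regression** with likelihood-ratio entry
   at p < 0.05 and removal at p > 0.10 (the common default of the
   statistics packages this workflow originated in; both thresholds are
   arguments). Each addition strictly increases the log-likelihood.
5. **Hosmer–Lemeshow** calibration: deciles of predicted risk (ties
   kept in one group, group count reduced with a warning when there are
   fewer distinct probabilities), statistic Σ(O−E)²/(E(1−E/n_g)),
   df = groups − 2.

Predictors are treated as numeric scores (one coefficient per factor):
exponentiating the published equations' coefficients reproduces their
printed per-stratum odds ratios to better than 0.2%, which pins down
this parameterization, and the intercept odds match the printed
constant rows the same way.

### Published equations

Four frozen logistic equations are shipped as `publishedModel()`:
Z1/Z2 (all patients) and Z3/Z4 (non-mucinous adenocarcinoma subgroup),
using coded RTV or coded ATV together with coded TC:

| model | cohort | intercept | volume coef | TC coef |
|-------|--------|-----------|-------------|---------|
| Z1 | all | −1.705 | −1.298 (RTV) | +1.2999 |
| Z2 | all | −1.620 | −1.235 (ATV) | +1.293 |
| Z3 | non-mucinous | −1.429 | −1.227 (RTV) | +1.164 |
| Z4 | non-mucinous | −1.323 | −1.19 (ATV) | +1.147 |

`evaluatePublishedModel()` returns `plogis(intercept + Σ coef·code)`,
the predicted pCR probability.

## ROC evaluation

`rocCurve()` sweeps every distinct score value plus ±∞ sentinels;
score ≥ cutoff is test-positive under positive orientation, and
negatively oriented predictors (volumes: *smaller* predicts pCR) use
score ≤ cutoff so reported cutoffs stay on the natural scale.
Auto-orientation picks the direction with AUC ≥ 0.5 and reports it. The
AUC is the trapezoidal area, identical to the Mann–Whitney pairwise win
fraction with ties counting one half (asserted exactly against a brute
force). The optimal cutoff maximizes the Youden index, ties broken
toward higher sensitivity and then the lower cutoff (comparisons are
rounded at 10 decimals so floating-point noise cannot flip a documented
tie-break); a closest-to-corner criterion is available. Reported
PPV/NPV are the empirical confusion-matrix values, which coincide
exactly with Bayes' formulas applied to the empirical sensitivity,
specificity and prevalence.

## Synthetic cohorts

No patient-level data are published for this problem, so the package
carries a first-class generator:

* **Geometry.** Each patient is an annular tumor around a cylindrical
  lumen: lumen radius 5–7 mm (a collapsed rectal lumen; chosen so the
  lumen volume spans ≈2–11 cm^3^, matching the spread of the printed
  ATV−RTV gaps with median ≈7 cm^3^), wall thickness 6–20 mm, length
  30–100 mm, angular coverage 0.6–1, and a seeded band-limited
  sinusoidal perturbation of the outer radius (0–2 mm) so walls stay
  smooth and connected. The default grid is 3.0 × 0.98 × 0.98 mm,
  routine pelvic CT. These ranges put the feature medians near the
  printed cohort characteristics (ATV ≈ 55, RTV ≈ 48, TSA ≈ 13 cm^3^,
  TML ≈ 6.6 cm, TMD ≈ 3.8 cm) and reproduce the raw ATV–RTV rank
  correlation of 0.99.
* **Covariates** are sampled independently of geometry (no joint
  distribution is published to emulate): gender 46:33, cT 11:54:14,
  cN 11:39:29, histology 69:3:7, CD44v6 33:21:17:8, age ≈ N(58.5, 9.5²)
  clipped to 30–80, CEA log-normal with median 4.27 ng/ml.
* **Outcome.** pCR ~ Bernoulli(plogis(−1.705 − 1.298·rtv_code +
  1.2999·tc_code)), i.e. the all-patient published equation as the
  generative truth; regression grade for non-pCR patients splits 2:3
  with probability 0.6/0.4 (only the pCR flag is analysed).
* **Two feature paths.** `method = "voxel"` builds the masks and runs
  the full volumetrics (the default and the end-to-end validation
  path); `method = "analytic"` uses the closed-form features of the
  ideal annulus, which is what the large Monte-Carlo suites use
  (coefficient CI coverage over 100 cohorts of 500, calibration level
  over 200 replicates) so they run in seconds. Both paths share the
  coding and outcome modules, so the generative coefficients are the
  truth for either.

What passing tests on these cohorts shows — and does not show: the
pipeline recovers known generative structure (signs, coefficient
coverage in 90–99%, selection of the true predictors, collinearity
exclusion of the volume pair) under geometry that is deliberately
idealized. Real tumors are not annuli, delineation noise is absent, and
covariates are independent of geometry by construction, so agreement
with the printed patient-level medians, AUCs or predictive-value panels
is neither expected nor claimed; those quantities would require the
original cohort.

## Numerical choices and degenerate inputs

* Voxel membership is center-inclusion; boxes and cylinder lengths use
  half-open axis intervals so aligned solids voxelize exactly.
* ITC voxels outside the ATV are reconciled by intersection with a
  warning; an empty ITC gives TSAI = 0 and RTV = ATV.
* A mask thinner than the contraction distance empties, so TSAO equals
  the whole mask volume — the thin-structure limit.
* Constant coded factors (e.g. histology inside the non-mucinous
  subgroup) are dropped from the model design with a message.
* Logistic fits flag separation at |coefficient| > 20 or
  non-convergence.
* A subgroup with a single outcome class skips its model block with an
  explicit reason rather than failing.
* Determinism: every stochastic step flows through an explicit seed
  (cohort simulation restores the caller's RNG state); identical
  configuration and seed give byte-identical JSON reports.

## Problem sizes used by the checks

The validation suites use: spheres of 10–20 mm at 0.3–1 mm isotropic
spacing (shell oracles on the finer grids, plain volumes at 1 mm);
brute-force morphology on random masks up to 15³ voxels; cohorts of
500–2000 patients (analytic path) for the statistical suites; and one
79-patient voxel cohort — the published cohort size — for the
end-to-end pipeline.

## Known limitations

* Shell surfaces are voxel estimates with the documented negative O(h)
  bias; mesh-based (marching-cubes) areas are out of scope.
* The generator produces masks only — no CT intensities, no DICOM.
* CEA above 5 ng/ml is a single stratum, exactly as coded upstream.
* Published-equation evaluation accepts only codes 1–5; extrapolation
  beyond the defining strata is refused rather than guessed.
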
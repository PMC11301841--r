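---
title: "Quantifying choroidal vascularity on OCT B-scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choroidal vascularity on OCT B-scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChoroidCVI)
```

## The measurement problem

High myopia stretches the posterior eye; the choroid — the vascular bed
between Bruch's membrane and the sclera — thins, and in diffuse
chorioretinal atrophy (DCA, the first stage of pathological myopia) both
its perfused lumens and its extravascular stroma are lost. Choroidal
thickness (ChT) alone cannot separate the two compartments. On an OCT
B-scan the lumens image dark and the stroma bright, so within a segmented
choroidal band one can count luminal area (LA), stromal area (SA), total
choroidal area (TCA = LA + SA) and the choroidal vascularity index
CVI = LA/TCA. This package computes those quantities per fovea-centered
region and meridian, corrects them for ocular magnification, and provides
the cohort statistics used to relate them to maculopathy grade, visual
function and diagnostic cut-offs.

## Pipeline model and assumptions

**Input geometry.** A B-scan is a matrix of non-negative reflectance
values, rows indexing depth, with known axial and (nominal) lateral pixel
spacing, the foveal center column, the meridian (vertical/horizontal) and
eye laterality. Boundaries come either from an external segmentation
(label image or per-column table — the primary path, standing in for a
checked and manually corrected automatic segmentation) or from
`baselineSegment()`, a deterministic edge finder for synthetic or
high-contrast scans. Per column the band is inclusive: the upper depth is
the first band row and the lower the last, so thickness is
`lower - upper + 1` pixels; serialized tables use 0-based depths while R
objects are 1-based. Columns with a missing or inverted boundary pair are
flagged invalid and excluded from every downstream sum — no interpolation
is invented — and the contributing fraction of columns is reported.

**Binarization.** The Niblack auto-local threshold classifies each band
pixel: `T = mu_w + k * sigma_w` with mean and *population* SD over a
square window centered on the pixel, lumen iff value < T (ties to stroma;
the rule is fixed). Three choices matter and are deliberate:

- *Window 51 px, k = -0.2 by default.* No single convention dominates the
  CVI literature; a window on the order of the band thickness with a small
  negative k suppresses speckle-driven false lumens while tracking axial
  signal decay. Both are exposed in `binarizationConfig()` and echoed in
  every output, so a study's choice is always on record.
- *Windows run over the full image, not masked to the band* — masking
  would shift thresholds within half a window of the boundaries; the
  binarize-then-overlay order matches how such images are processed in
  practice.
- *Reflective edge padding* avoids threshold bias where the band
  approaches the image border.

Because T transforms affinely with the data, labels are invariant under
any positive affine intensity rescaling — the suite property-tests this,
and checks the whole operator pixel-for-pixel against a brute-force
double-loop oracle.

**Magnification correction.** OCT lateral scales vary with axial length
(AL). Following Bennett's formula t = p·q·s with q = 0.01306 (AL − 1.82)
and the device constant p fixed by unit magnification at AL = 24.4 mm,
lateral distances are multiplied by (AL − 1.82)/22.58. The axial dimension
is optical-path based and left uncorrected, so ChT is factor-invariant,
LA/SA/TCA scale linearly in the factor, and CVI cancels it entirely.

**Regions.** The analyzed section spans ±3 mm of *corrected* distance from
the fovea: C [−0.5, 0.5), parafovea ±[0.5, 1.5), perifovea ±[1.5, 3.0),
half-open with the left edge included so columns are never double-counted;
a column belongs to the region containing its center. Defining the window
in corrected millimeters keeps region widths physically comparable across
eyes of different AL; the cost is that the nominal "6-mm" scan may not
cover ±3 mm in short eyes, in which case the truncated share of each
region is reported (`clamped_fraction`) rather than silently ignored.
Perifoveal LA/SA are additionally reported divided by 1.5 to remove the
width difference when regions are compared. Meridian LA/SA are *totals*
over the section (region values sum to them exactly), so
LA + SA ≈ ChT(mm) × 6 mm — this convention reproduces the magnitudes on
which published diagnostic cut-offs for meridian areas sit (a few tenths
of a mm², versus thickness-like numbers if means were used), and the
package treats it as its fixed definition. On the horizontal meridian the
negative (lower-column) side is nasal for OD and temporal for OS, so
fellow eyes mirror.

## Cohort statistics

Both eyes of a subject enter the analysis, so every inferential step
accounts for within-subject correlation:

- **Group comparisons** (`compareGroups()`): marginal linear model of a
  metric on maculopathy category plus adjusters (age and AL by default),
  fit by iterated GLS with an exchangeable working correlation estimated
  from the data; variance by the robust sandwich with the Mancl–DeRouen
  small-sample bias correction and a t reference on (clusters −
  parameters) degrees of freedom. This combination holds the type-I error
  of pairwise contrasts near nominal at a few hundred subjects, which the
  suite verifies over 500 null replicates. The three pairwise contrasts
  are Bonferroni-adjusted (p × 3, capped at 1). The fitter is authored
  in-package; with one eye per subject and no adjusters it reduces exactly
  to OLS, which the tests use as an oracle.
- **DCA logistic models** (`fitDcaLogistic()`): DCA indicator on one
  standardized choroidal predictor plus standardized age and AL and
  gender, via `glm` with subject-clustered robust errors
  (`sandwich::vcovCL`). Continuous variables are Z-scored over the
  analyzed eyes (the reference sample is a declared choice, recorded in
  the output), so odds ratios are per sample SD and invariant to predictor
  rescaling. Perfect separation raises an explicit error instead of a
  silent coefficient blow-up.
- **Visual-function models** (`fitMdLinear()`): mean deviation on age,
  height, AL, corneal curvature and one area metric, restricted to
  reliable visual-field tests, in all eyes or the non-pathological
  (C0+C1) / pathological (C2) subsets, with cluster-robust errors and
  standardized betas.
- **Diagnostic cut-offs** (`rocCutoff()`, `ageStratifiedTable()`): AUC as
  the pairwise concordance statistic (ties half-weighted), oriented so
  AUC ≥ 0.5 — for choroidal metrics, lower values indicate disease; SE and
  95% CI by DeLong's method (a declared choice; distribution-free and
  standard for this reporting style). Candidate cut-offs are midpoints
  between consecutive sorted unique values plus open ends; the Youden
  index J = sensitivity + specificity − 1 picks the cut-off, ties broken
  toward higher sensitivity (screening context), then the smaller
  threshold, and the report is clamped to the observed range. Age strata
  are 18 ≤ age ≤ 30, then 30 < age ≤ 40, 40 < age ≤ 50, 50 < age ≤ 60;
  an empty or one-class stratum yields a missing row, not a failure. The
  implementation is checked against brute-force pair enumeration and an
  independent DeLong implementation (pROC).
- **Exclusions** (`applyExclusions()`): eyes carrying any `excl_*` flag
  are removed with an itemized per-reason, per-side ledger. One eye may
  carry several reasons, so reason counts may exceed eyes removed; the
  survivor count always equals input minus flagged eyes.

Missing covariates are handled complete-case per model with the analyzed
n reported; no imputation is performed.

## The synthetic generator: what it emulates, and what not

Real cohort data of this kind are not publicly deposited, so validation
rests on synthetic data whose truth is exact.

**B-scans** (`simulateBScan()`): a band between smooth boundaries (sums of
2–4 low-frequency sinusoids with random phases — smooth, cheap, and
realistic at the millimeter scale), elliptical lumens (axis-aligned,
wider than tall, semi-axes uniform in 48–336 µm × 12–48 µm, the caliber
range of Sattler/Haller vessels) placed uniformly and merged where they
overlap, clipped to the band so the truth mask stays exact, added until
the lumen-pixel fraction is within ±0.02 of target; then unit-mean
multiplicative gamma speckle over the whole image. Choices worth
recording:

- *Speckle shape 80* (CV ≈ 0.11). The images a CVI pipeline consumes are
  registered multi-frame averages; raw single-frame speckle (CV ≈ 0.5,
  shape ≈ 4) would make the two reflectance classes statistically
  inseparable for any local threshold and does not represent the analyzed
  material. The parameter is an uncalibrated knob — no scanner's intensity
  statistics are claimed — and single-frame conditions can be emulated by
  setting it low.
- *Background 40, just below the lumen mean (55) and far below stroma
  (155).* The choroid borders tissue (outer retina above, scleral shadow
  below), not void; against a near-black background, windows straddling
  the band edge would drag thresholds below the lumen level and
  misclassify edge lumens — an artifact of the phantom, not of the method.
- For a fixed seed, raising the target only appends ellipses, so the
  achieved fraction is monotone in the target — handy for response tests.

The generator does **not** emulate: vessel connectivity or flow, 3-D
volumes, retinal layers, RPE humps, parapapillary atrophy, shadowing, or
depth-dependent signal decay. Passing recovery tests therefore shows the
pipeline is correct *given its contract* (band-limited bimodal reflectance
under mild multiplicative noise); it does not certify accuracy on scans
whose contrast or artifacts fall outside that contract.

**Cohorts** (`simulateCohort()`): per-eye maculopathy categories drawn
from a configurable mix (default 6.6/76.0/17.4% for C0/C1/C2); continuous
traits from per-category normals with a shared subject-level effect
(value = m_g + s_g(√ρ·z_subject + √(1−ρ)·z_eye), default ρ = 0.7),
matching the exchangeable working-correlation assumption of the analysis.
Default trait distributions follow a hospital-based adult high-myopia
cohort (AL 26.3→27.9 mm, vertical ChT ≈ 230→105 µm and nasal-perifoveal
ChT ≈ 160→45 µm from C0 to C2, CVI rising slightly with severity); areas
derive from thickness and CVI so internal identities hold by
construction. MD follows a linear link on age, height, AL, corneal
curvature and LA_V (default coefficients 0, 0.022, −0.440, −0.311, 1.512
with intercept 17.247 and residual SD 2 dB). Age, height and gender are
subject-level (taken from the worse eye's category). Because a DCA label
cannot simultaneously equal the C2 category *and* follow a free logistic
link, `dcaMode` resolves the tension explicitly: `"category"` (default)
sets DCA = C2 so metric associations arise from group structure;
`"logistic"` draws DCA from
logit p = b₀ + b·z(LA_V) (defaults −2.2 and log 0.1) for
parameter-recovery tests with a known per-SD log-odds ratio.

## Numerical choices and degenerate inputs

- Window statistics use integral images; population SD with
  `pmax(·, 0)` guarding rounding; a perfectly uniform image yields σ = 0,
  T = value, and the strict `<` tie rule labels everything stroma.
- A region or stratum with no usable data reports missing (NA), never
  zero; an empty band, a uniform image fed to the segmenter, one-class
  ROC input, a singular design, and perfect separation all raise explicit
  errors naming the condition.
- CVI is undefined (NA) exactly when TCA = 0.
- Seeds: every generator takes an explicit seed and restores the caller's
  RNG state; identical configuration and seed reproduce outputs
  bit-for-bit.

## Validation problem sizes

The test suite exercises: the brute-force Niblack oracle on 100 random
images up to 32×32; lumen-fraction recovery on 20 B-scans per target
fraction {0.2, 0.4, 0.6} (mean |CVI − truth| ≤ 0.05 under the default
configuration); AUC against pair enumeration on 50 random data sets up to
n = 200; logistic OR recovery at 2000 subjects and linear link recovery
at 1500; and null calibration of the group contrasts over 500 replicates
of 150-subject cohorts. These sizes give stable pass/fail behavior at
interactive runtimes while staying far above the granularity of the
effects tested.

## Known limitations

- The baseline segmenter is a stand-in for a trained segmentation model
  and is only suitable for high-contrast, artifact-free scans; the
  intended use supplies externally checked boundaries.
- The Niblack parameters are conventions, not estimates; results should
  be reported together with the emitted configuration.
- Whether a "6-mm" section means nominal or corrected millimeters is
  ambiguous in the field; this package fixes corrected millimeters and
  reports clamping, but cross-study comparisons should check the
  convention.
- The exchangeable GEE fitter covers the Gaussian case used for group
  comparisons; the logistic and linear tables rely on cluster-robust
  errors rather than a full GEE refit — the minimal structure that honors
  two correlated eyes per subject.
- Axial distances carry no refraction-based correction.
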
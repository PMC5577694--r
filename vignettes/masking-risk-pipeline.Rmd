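---
title: "Predicting mammography failure from texture features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mammography failure from texture features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammotex)
```

## The model

A tumor is *masked* when it is visible on ultrasound but assigned an
unsuspicious mammogram. The risk model is a logistic regression on
clinical covariates plus one mammographic-density term:

$$z = \beta_0 + \beta_{age}\,\mathrm{age} + \beta_{bmi}\,\mathrm{BMI}
      + \beta_{surg}\,\mathrm{surgery} + \beta_{meno}
      + \beta_{tech} + \beta_{pmd}\,\mathrm{PMD}, \qquad
  \Pr(\text{masked}) = \frac{e^z}{1 + e^z},$$

with reference categories premenopausal, no previous surgery and analog
technique (coefficient 0). PMD — the percentage of breast-region pixels
at or above a gray threshold — enters linearly, whether it is the
semi-automatically observed value or a texture-based prediction; no
splines or interactions are used, so a single slope summarizes the
density effect. Fitting is plain maximum likelihood (IRLS, convergence
tolerance $10^{-10}$, at most 100 iterations), standard errors from the
observed information.

The scientific question the package operationalizes is: *how much of the
observed-PMD model's discrimination survives when PMD is replaced by an
automatic texture-based prediction?* Answering it requires three
ingredients: a feature extractor, a family of tuned regression models for
PMD, and an evaluation design that never lets validation data touch model
building.

## Texture features (363)

All features are computed from pixels inside a binary breast mask; the
inventory is data-driven (`feature_registry()`) with the naming scheme
`<family>.<statistic>[.<qualifier>]`:

* **Moment-based (76)** — mean, variance, skewness, kurtosis; normalized
  central moments $m_k = \mu_k/\sigma^k$, $k = 2..19$; and three
  compressive transforms of each NCM
  ($\operatorname{sign}(m)\log(1+|m|)$,
  $\operatorname{sign}(m)|m|^{1/k}$, $m/(1+|m|)$) that tame the
  explosive growth of high orders. A constant region has $\sigma = 0$;
  skewness, kurtosis and all NCMs are then *defined* as 0 so feature
  vectors stay finite on degenerate fixtures.
* **Histogram (16)** — relative frequencies over 16 equal-width gray
  categories spanning [0, 256); they sum to 1.
* **Markovian (93)** — distance-1 co-occurrence matrices at orientations
  0°, 45°, 90°, 135° (0° = east, 90° = north; pairs counted in both
  directions, so matrices are symmetric and normalized). Per
  orientation: the 13 classical co-occurrence statistics plus 4
  sum-histogram and 5 difference-histogram statistics; plus 5
  orientation averages. Quantization uses G = 64 levels. A correlation
  with zero marginal variance is defined as 0.
* **Regional (48)** — for 8 thresholds {32, 64, …, 224, 256}: binarize
  `gray >= t`, find 4-connected components inside the mask, and report
  log(1+count), mean/SD area, mean compactness $4\pi A/P^2$, the largest
  region's share of the mask, and the mean region gray. At t = 256 (and
  whenever no pixel qualifies) all six statistics default to 0.
* **Run-length (60)** — 15 statistics of the run-length distribution per
  direction at G = 16 (SRE, LRE, GLN(N), RLN(N), RP, GLV, RLV, LGRE,
  HGRE and the four joint emphases), with runs truncated at the mask
  boundary and 1-based gray levels so low/high-gray emphases are
  well defined.
* **Fourier (33)** — power-spectrum shares in 16 radial annuli up to the
  Nyquist frequency and 16 angular sectors of 11.25°, plus the spectral
  centroid radius. The image is cropped to the mask bounding box and
  non-mask pixels are replaced by the masked mean ("mean-fill
  windowing") so the mask edge does not dominate the spectrum.
* **Wavelet (37)** — 4-level separable Daubechies-4 decomposition with
  periodic boundaries (odd dimensions padded by edge replication):
  per-level detail energies, energy fractions and sub-band Shannon
  entropies, plus the final approximation energy.

The per-family statistic sets were chosen as the field-standard
inventories satisfying the fixed family counts 76/16/93/48/60/33/37;
because the registry is data-driven, individual definitions can be
revised without touching extractor logic. G = 64 for co-occurrence and
G = 16 for run length balance matrix sparsity against gray-level
resolution at typical breast-region sizes.

## Preselection

Features are pruned once on the complete table, before any
cross-validation, using no outcome information (so it cannot bias model
assessment): features with |sample skewness| > 10 are dropped (an
automated stand-in for visual box-plot screening), the rest are randomly
ordered and any feature with Spearman |ρ| > 0.98 against a higher-ranked
retained feature is removed. The *absolute* correlation is deliberate: a
sign-flipped duplicate is as redundant as an identical one. The basic
intensity features (4 central moments, 16 histogram bins) are kept
unconditionally. Constant features have undefined Spearman correlations
and are treated as uncorrelated.

## PMD prediction and tuning

Four techniques, each with one tuning parameter λ:

| method | λ | default grid |
|---|---|---|
| univariate selection | number of top-F-test features | 1..min(150, p, n−2) |
| lasso | penalty in (1/2n)·RSS + λΣ\|β\| | 50-value log path from the entry value |
| boosting (L2Boost) | iterations | 30 log-spaced values in 1..2000 |
| random forest | candidate variables per split | p·{0.1, 0.2, 1/3, 0.5} |

λ is chosen by 10-fold cross-validation on training data (fold
assignment fixed by seed and shared across the grid; smallest mean
held-out MSE wins, ties to the smallest λ). The forest uses out-of-bag
error instead, with 500 trees. The boosting step size is 0.1 with an
iteration budget up to 2000 — many small steps, matching how
component-wise boosting is normally run and letting selection stay
gradual. Features are standardized inside lasso and boosting so the
penalty and the selection are scale-fair; coefficients are
back-transformed. Boosting tuning evaluates the whole iteration grid
from a single path per fold. Predicted PMD values are *not* clipped to
[0, 100]: the masking model consumes them linearly, and clipping would
distort exactly the extreme-density patients that matter most.

Tie-breaks everywhere are deterministic: smallest λ, then first feature
in registry order.

## Evaluation design

`repeated_double_cv()` implements repeated double (nested)
cross-validation: an inner loop (above) chooses λ on the outer-training
two-thirds, the PMD model is fitted there, predicted PMD is attached to
both parts, all masking logistic models (predictor-free null,
clinical-only, one per PMD method, observed-PMD) are fitted on the
training part, and Brier MSE, Mann–Whitney AUC (ties counted 1/2),
continuous NRI versus the clinical model and discovery rates are
computed on the held-out third. With 3 outer folds and 100 repetitions
the full design yields 300 records per model, aggregated by plain
mean/SD.

Two design choices deserve a note. First, outer folds are **stratified
by masking status**: at ~8% prevalence an unstratified 3-fold split has
a real chance of an event-free fold, which would make AUC and NRI
undefined; stratification is a deviation by necessity and changes
nothing else. Second, NRI ties (identical old and new risk) count toward
neither direction, the standard continuous-NRI convention; on tie-free
records the identity NRI = (2·P(up|event)−1) + (2·P(down|nonevent)−1)
holds exactly and is asserted in the tests.

Every random choice derives from a single seed through a counter-based
stream, so reports are bit-reproducible across machines.

## The synthetic-data generator

Nothing in the pipeline requires real images, so the generator must
produce data with the statistical structure the analysis assumes.

* **Images**: a Gaussian white-noise field smoothed by an isotropic
  Gaussian kernel (default scale 8 px; FFT convolution) inside a
  half-ellipse "breast" mask anchored at the left frame edge (~60% of
  the frame). A monotone per-image rescaling maps the field below the
  (1 − target/100) quantile to gray [0, 127] and above it to [128, 255],
  so the fraction of mask pixels ≥ 128 — the package's density
  definition — hits the target within about a percentage point. The
  smoothing gives spatially correlated, cloud-like texture, so
  co-occurrence and run-length features are non-degenerate; the fixed
  threshold 128 stands in for the per-image threshold a human reader
  would choose.
* **Cohorts**: age, BMI and PMD from (truncated) normals, surgery and
  technique Bernoulli, a three-level menopausal/HRT factor — defaults
  describing a hospital-based diagnostic mammography population (age
  59.6 ± 12.6 y, BMI 26.2 ± 4.7 kg/m², PMD 35.8 ± 19.0% truncated to
  [0, 100] by resampling, 13% surgery, 24/56/20% menopausal mix, 39%
  digital). Covariates are sampled independently — a simplification, as
  age, BMI and density are correlated in real cohorts. Masking is then
  drawn from the logistic model above with the reference coefficient set
  `default_masking_coefficients()` (PMD slope 0.032 per percentage
  point), so simulate → refit is a clean parameter-recovery experiment.
* **Full studies**: `simulate_masking_study()` renders one image per
  patient at `target_pmd = pmd_observed + noise` (sd 10 percentage
  points, truncated). The noise emulates the imperfect agreement between
  a semi-automatic density reading and the image content; it is what
  makes texture-based prediction attain validation R² ≈ 0.7 — the
  realistic regime for this problem — instead of reproducing observed
  PMD as an identity (the upper histogram bins of a noise-free synthetic
  image sum to exactly the thresholded density). With it, the double-CV
  AUC ordering *clinical < clinical+predicted ≤ clinical+observed*
  emerges from the data rather than being built in.

What passing tests on these data do **not** show: performance on real
mammograms. The generator has stationary texture, no anatomy
(pectoral muscle, skin line, vessels), no acquisition artifacts, and
independent covariates; absolute MSE/AUC levels on real cohorts will
differ. The synthetic results validate the *machinery* — contracts,
estimators, leakage-freedom, orderings — not clinical performance.

## Numerical choices and degenerate inputs

* σ = 0 moments, zero-variance correlations, empty region sets and
  zero spectral power all default to 0, keeping every feature finite on
  constant images.
* The lasso path is warm-started from the penalty's entry value and
  truncated at the requested λ (convergence threshold 10⁻¹¹), which
  reproduces OLS at λ = 0 to ~10⁻⁸ and the single-predictor
  soft-threshold closed form to machine precision.
* Logistic fits abort with a diagnostic on non-convergence or diverging
  coefficients (|β| > 50, the practical signature of complete
  separation); covariates that are degenerate in a training fold
  (single factor level, zero variance) are dropped from that fit and
  keep coefficient 0.
* Inner folds are shared across the whole λ grid so the tuning
  comparison is paired.

## Problem sizes used by the test suite

The suite exercises the full design at reduced scale: images of 48–64 px
(256 px for the extractor contract), cohorts of 100–2000 for harness
properties, 100 replicate cohorts of 10,000 for coverage of the
masking-model recovery, one cohort of 200,000 for tight parameter
recovery, and the full pipeline property (1334 patients, 64-px images,
10 repetitions × 3 folds, lasso as the predicted-PMD method) for the
model-ordering check. These sizes are the package's own trade-off
between statistical resolution and a test suite that stays pleasant to
run; all of them are one-line changes in the corresponding
configuration objects.

## Known limitations

* The seven-family inventory is a faithful reconstruction constrained by
  the family counts; an independent implementation of the same families
  may differ in individual statistics.
* PMD truncation to [0, 100] by resampling slightly shifts the realized
  mean/SD relative to the nominal normal parameters (about +1.2
  percentage points at the default settings); tests compare against the
  analytic truncated-normal moments.
* No DICOM ingestion, film-digitizer emulation or reader-disagreement
  modelling; analyses start from 8-bit grayscale images with masks.
* Discovery rates are computed in a diagnostic-cohort setting; they are
  not screening-population specificity estimates.
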
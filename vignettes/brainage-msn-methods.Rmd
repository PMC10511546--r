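---
title: "Brainage from morphometric similarity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brainage from morphometric similarity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainagemsn)
```

## The problem

In typically developing children, regional cortical morphometry changes
along well-programmed trajectories: cortical thickness thins through late
childhood and adolescence, grey-matter volume follows an inverted-U, and
curvature-based measures are comparatively stable over this window. A
*Brainage* model learns the multivariate association between such
measures and chronological age in healthy subjects, so that the age it
predicts for a new scan can be read as the apparent developmental status
of that brain. The signed difference between predicted and chronological
age (*Brainage delta*) is then a candidate individual-difference measure.

This package implements a full Brainage evaluation pipeline in which the
competing predictors are (i) each of seven regional morphometry features
over the 68-region Desikan-Killiany atlas, (ii) all of them together, and
(iii) two network-level summaries of a per-subject *morphometric
similarity network* (MSN): its normalised nodal strengths and its 2278
edge weights. The MSN of a subject correlates, for every pair of regions,
the regions' z-scored 7-feature profiles, so an edge measures how
anatomically alike two regions are in that subject; its organisation
matures with age, which is what gives the network features predictive
value.

Everything runs on a synthetic multi-site cohort generator with known
ground truth, so every stage of the pipeline is testable without any
imaging download.

## The synthetic cohort generator

`generate_cohort()` draws, per subject and region,

```
value = (baseline + trend(age) + subject intercept + coupling + site offset)
        * site scale + noise
```

* **baseline**: a fixed per-region, per-feature level drawn once per
  cohort around realistic Freesurfer-scale means (e.g. thickness ~2.7 mm,
  volume ~5800 mm^3).
* **trend(age)**: a common linear (optionally quadratic) trend per
  feature. Defaults place the dominant slopes on cortical thickness
  (-0.03 mm/yr) and volume (-55 mm^3/yr); curvature-type features get
  near-zero slopes. This is the feature-specific ordering the evaluation
  is designed to detect.
* **subject intercept**: a per-subject, per-feature offset shared across
  regions. It represents stable biological individual differences and is
  what keeps single-feature models honestly imperfect: averaging over 68
  regions removes the iid noise but not this term.
* **coupling**: a rank-1 latent term `g * w(age)_r * c_f` whose region
  loadings rotate with age, `w(age) = cos(theta) w1 + sin(theta) w2`,
  `theta = coupling_age_slope * (age - age_mean)`. Because the loading
  pattern rotates, the correlation structure between regional profiles -
  and therefore the MSN edge weights - drifts with age; with
  `coupling_age_slope = 0` expected edge weights are age-independent
  (a property the test suite checks over 50 seeds). The feature contrast
  `c` loads mainly on thickness and volume (coordinated thickness-volume
  maturation), which keeps curvature-type features close to
  age-uninformative.
* **site effects**: additive offsets and multiplicative factors per site
  and feature (drawn or supplied), plus site-batched QA metrics, so that
  harmonisation and within-site QC have real work to do.

Ages are drawn from a truncated normal. The parent parameters are
moment-matched so that the *marginal* mean and SD of the drawn cohort hit
the configured values (12.4 +/- 2.5 yrs inside 6.5-16.9): truncation
shrinks the SD of a naive draw by about 10%, and the configured values
describe the cohort, not the parent. Sex is ~79% male, IQ is 110 +/- 15
with ~6% missing, and a small fraction of subjects (~3.9%) get three QA
metrics degraded by 3 within-site SD in the quality-worsening direction
to exercise the QC filter.

**What the generator does not emulate.** Real cortical geometry and
spatial autocorrelation; region-specific age trajectories; site-by-age
confounding (sites sample the same age distribution); and a concentration
of the age signal on the *strongest* MSN edges. The last point matters
for density thresholding: in real data the reported experience is that
keeping only the top 5% of |edges| predicts as well as the full network,
which presumes the informative edges are among the strong ones. The
generator's coupling spreads signal across edges of all magnitudes, so on
generator cohorts sparse-density models lose accuracy; the
"equal performance under thresholding" property is therefore tested on a
constructed fixture that satisfies the premise, and the density
experiment script reports whatever the generator actually produces.

## Quality control

The six spatial QA metrics (CNR, EFC, FBER, FWHM, Qi1, SNR) are z-scored
within site and re-signed so larger is always better; a metric fails
below z = -1.5 and a subject is kept with at most one failure. Two
details are deliberately configuration-exposed rather than guessed: the
SD convention (population SD by default, `ddof = 0`) and each metric's
raw quality orientation (EFC, FWHM and Qi1 are "higher is worse" by
default).

## Harmonisation

`fit_harmonization()` is a location/scale batch-effect model in the
ComBat family, applied to the subjects x 68-regions slab of one feature
at a time while protecting age: regions are standardised with a pooled
regression on site indicators plus age, per-site location and scale
estimates are shrunk with the parametric empirical-Bayes scheme (normal
prior on locations, inverse-gamma on scales, priors moment-matched across
regions), and the data are reconstructed with the age fit added back. The
EB iteration reproduces the reference implementation's fixed point and
stopping rule, and the test suite verifies agreement with `sva::ComBat`
(protecting age through its `mod` argument) to within 1e-5; `eb = FALSE`
gives the closed-form non-EB solution used in exact tests. Harmonisation
is fitted on all QC-included subjects before any train/test split,
mirroring the pipeline order the evaluation assumes.

## MSN construction

Per subject: z-score each feature across the 68 regions (sample SD;
columns of constant value are a hard error naming subject and feature),
correlate every pair of length-7 regional profiles, and keep the full
signed matrix. Zero-variance regional profiles are an error rather than a
silent NaN edge. Edge vectorisation is the upper triangle in fixed
lexicographic region order (length 2278). Density thresholding keeps the
`round(d * 2278)` edges of largest absolute weight - `round()` is
round-half-even, and the rounding rule is a documented implementation
choice - with deterministic tie-breaking by (|w| desc, i, j). Degree
counts surviving edges; normalised nodal strength is the sum of surviving
signed weights over the degree (the node's mean surviving edge weight
when unthresholded); global strength is the mean nodal strength. The
density grid is configuration-driven with both the 5-50% and 5-40%
presets, since both appear in practice.

## Splits

Training and test cohorts are formed by age-stratified under-sampling:
half-year bins from 9 yrs upward, one merged bin below 9 (the thin lower
tail), a training target of `floor(0.75 n)` filled with equal per-bin
quotas, deficits redistributed round-robin to bins that still have
members, remainder = test. This flattens the training age distribution
where the data allow, and reproduces the familiar cohort arithmetic
(327 -> 245/82, then 245 -> 204/41 at 5:1). The internal 5:1 refinement
is simple random (not re-stratified) - the evaluation design does not
require it, and the choice is recorded in the run manifest. The collapse
boundary is `[min, 9.0)` and configurable. Whether the test cohort
should itself be re-stratified is an open design point; here it is the
under-sampling remainder, which is what produces the characteristic
slightly-younger test cohorts.

## Kernel age models

Both models operate on column-standardised inputs (training means/SDs)
and a unit-diagonal radial-basis kernel: `rbfdot`
`k = exp(-sigma ||x - x'||^2)` or `laplacedot`
`k = exp(-sigma ||x - x'||)`.

* **Bandwidth**: median heuristic - `sigma = 1/median(||x - x'||^2)`
  (rbf) or `1/median(||x - x'||)` (laplace) over a deterministic
  subsample of training pairs. No reference bandwidths exist for this
  problem; the heuristic is the standard default and is recorded in the
  model object.
* **GPR**: dual weights `alpha = (K + noise_var I)^{-1} ytilde` by
  Cholesky with 1e-8 jitter, where `ytilde` is the response standardised
  to zero mean and unit variance. Standardising the response makes the
  large-noise limit the training mean (not zero years), and
  `noise_var = 1` on that scale - noise variance equal to the kernel's
  unit prior variance - matches the default regularisation of the kernel
  toolkits this literature runs on. Near-zero `noise_var` turns the model
  into an interpolator (train R^2 = 1), which is exactly the overfitting
  signature the evaluation is designed to expose on the validation
  cohort, so the default deliberately sits well away from it. Both limits
  are tested numerically.
* **RVR**: sparse Bayesian regression over the kernel basis (one basis
  function per training point, no intercept; the basis is rich enough to
  absorb the mean). Per-weight precisions and the noise precision follow
  the evidence-framework updates; basis functions with precision above
  1e9 are pruned; iteration stops when the active log-precisions move
  less than 1e-6 or at 1000 iterations. The retained relevance vectors
  are a subset of the training set by construction. With its near-zero
  effective noise on small cohorts RVR routinely drives training R^2 to
  ~1.0 while validating worse than GPR - the characteristic pattern the
  model-selection stage exists to catch.

## Evaluation

`predicted_r2 = 1 - MSE(pred, obs) / MSE(obs, mean)` with the
*evaluation cohort's own mean* in the denominator, so "predict the mean"
scores exactly 0 and negative values mean worse-than-mean; the training
mean is available as a switch. Selection picks the best validation
predicted R^2 per feature set with deterministic tie-breaks (lower MAE,
then GPR before RVR, laplacedot before rbfdot). Robustness re-runs
split -> train -> test over fresh partitions (the selected cell stays
fixed; re-running selection inside each partition is a config switch left
off, since the question is the stability of the chosen model). The
permutation test holds the split fixed, permutes training ages only,
retrains, and evaluates against the true test ages; the p-value uses the
add-one estimator `p = (1 + #{null >= observed}) / (1 + n_perm)` - never
exactly zero, and exactly uniform under the null - with the observed
statistic being the mean resampled R^2. Day-to-day and test sizes are 20
partitions / 99 permutations; the release-scale configuration is 100 /
1000. Note that the smallest attainable p-value is `1/(n_perm + 1)`, so
a scaled-down run needs at least 200 permutations before anything can
clear the Bonferroni threshold 0.05/10 = 0.005 (the acceptance script
uses 249 for exactly this reason).

## Brainage delta and bias screens

Delta is **signed** (predicted - actual). The screens require the sign:
shrinkage-regularised models overestimate young and underestimate old
subjects, so delta correlates negatively with age - a screen that an
absolute difference could not express. Each model's test-cohort delta is
screened for: EFC (motion proxy) and IQ associations by Pearson and
Spearman partial correlations controlling actual age (first-order
partial-correlation formula; Spearman is the same formula on ranks; t
transform with n-3 df; IQ missing values dropped pairwise with per-row
n), the delta-age Pearson correlation itself, and a sex effect from
`delta ~ sex + age`. With ten models that is 50 continuous tests plus 10
sex tests, and the single Bonferroni threshold 0.05/60 = 0.000833 is
applied across the screen - the accounting that produces the published
denominator, exposed in configuration.

## Orchestration and reproducibility

`run_experiment()` executes generate -> QC -> harmonise -> MSN -> feature
sets -> split -> selection -> one held-out test evaluation -> robustness
-> delta screens, with every stage seed derived from the master seed and
recorded, stage timings and cohort sizes in a JSON manifest, and an
access counter proving the test cohort is touched exactly once per
feature set in the main evaluation. The numbered scripts under
`analysis/` walk the same stages as independently re-runnable steps over
on-disk artifacts; they and the package functions are the interface - no
shell wrapper is needed for an analysis of this shape.

## Problem sizes used by the test suite

Unit and property tests run on cohorts of 10-500 subjects over 2-6
sites. The heavier checks use: 50 seeds at n = 500 for harmonisation and
sex-offset parameter recovery; 200 mini-experiments with 99 permutations
each (n = 48, 6 age-independent features) for permutation calibration;
and 50 runs at n = 300 with 20 resampling partitions for the
thickness >= edge weights >= curvature ordering and the negative
delta-age correlation. These sizes are the package's scaled-down study
conditions; the full-scale configuration (100 partitions, 1000
permutations) is available through `default_run_config(paper_scale =
TRUE)`.

## Known limitations

* The generator's coupling mechanism is rank-1 and rotation-based; real
  morphometric covariance matures in richer ways, and the generator's
  edge signal is not concentrated on strong edges (see above).
* No hyperparameter optimisation: bandwidths come from the median
  heuristic and the GPR noise level is a fixed default, as in the
  toolkits this pipeline mirrors; marginal-likelihood optimisation is a
  non-goal.
* Harmonisation covariates are site and age only; scanner protocol or
  longitudinal structure is out of scope.
* Passing the qualitative ordering tests on synthetic cohorts shows the
  pipeline detects the signal structure it injects - it is evidence about
  the code, not about any real cohort.
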
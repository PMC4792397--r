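---
title: "Methods: ReHo-based MVPA for minimal hepatic encephalopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ReHo-based MVPA for minimal hepatic encephalopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the processing
procedure, every tunable parameter with its default and rationale, and
the numerical conventions adopted where more than one defensible choice
exists. Code chunks are illustrative and not evaluated when the
vignette is built.

## 1. Problem

Cirrhotic patients are split into two groups by the Psychometric
Hepatic Encephalopathy Score (PHES): minimal hepatic encephalopathy
(MHE, PHES below an integer cutoff) and no hepatic encephalopathy
(NHE). The goal is single-subject classification from resting-state
fMRI via regional homogeneity (ReHo) maps, plus localization of the
discriminative pattern and its relation to disease severity.

Throughout, MHE is encoded `+1` (the positive class: sensitivity =
detected MHE fraction) and NHE `-1`.

The cutoff itself is the largest integer strictly below
mean − 2·SD of a normative PHES sample:

```{r}
mhe_cutoff(-0.36, 2.04)   # ceiling(x - 1) = -5
```

## 2. Preprocessing

`preprocess_volume(vol, mask, tr_seconds, preprocess_config())` applies,
per in-mask voxel time series:

* **Discard** the first `n_discard = 10` volumes (signal-equilibration
  convention).
* **Linear detrend** by least squares against time.
* **Band-pass 0.01–0.08 Hz** as a brick-wall FFT filter: frequency bins
  with `low <= f <= high` (inclusive) are kept, everything else zeroed,
  then inverse-transformed. This is the REST/AFNI convention for ReHo
  pipelines; an IIR filter (e.g. Butterworth) would introduce phase
  and edge behavior that the downstream rank statistics do not need.
  For even series length the Nyquist bin is treated like any other bin.

`motion_qc` flags a subject when **any** translation axis exceeds 3 mm
or any rotation axis exceeds 3.0° (strict inequality, per-axis maxima
of absolute values). `run_pipeline` excludes flagged subjects and logs
the per-axis reason.

## 3. ReHo: Kendall's coefficient of concordance

For voxel $v$ with neighborhood of size $K$ (the voxel plus its face /
face+edge / face+edge+corner neighbors, $K \in \{7, 19, 27\}$,
default 27) and $n$ time points,

$$W = \frac{12 \sum_t \left(R_t - \tfrac{K(n+1)}{2}\right)^2}{K^2 (n^3 - n)},$$

where $R_t$ is the rank sum across the $K$ series at time $t$ (ranks
computed within each series; ties get average ranks). `compute_kcc`
optionally subtracts the tie correction $K \sum_j T_j$ from the
denominator; the default leaves it off because band-passed continuous
data are tie-free almost surely, and the untied form matches the
classical ReHo implementation. The whole-brain map is computed in one
pass as a sparse matrix product of the rank matrix with the voxel
adjacency matrix (`reho_volume`), which the test suite verifies against
a brute-force per-voxel oracle to 1e-12.

**Edge policy** (`edge_policy`): at mask borders a voxel has fewer than
$K-1$ available neighbors. `"available"` (default) computes $W$ over
whatever neighbors exist (requiring at least 2 series), so the map
covers the whole mask; `"skip"` restricts to voxels with a full
neighborhood, reproducing implementations that shrink the support.
Both are exposed because published pipelines differ and the choice
visibly changes map support.

**Normalization and smoothing order.** `normalize_reho` divides by the
in-mask mean (so every subject's map has in-mask mean exactly 1 —
an invariant the acceptance tests assert), and smoothing happens
*after* normalization (`smooth_volume`, Gaussian FWHM 8 mm, separable
truncated-4σ sampled kernel, re-masked afterwards). Smoothing borrows
zeros from outside the mask, so the smoothed map's in-mask mean is
slightly below 1 near edges; normalizing first keeps the invariant
well-defined on the unsmoothed quantity.

## 4. Synthetic cohort generator

`generate_cohort(cohort_spec(...), dir)` writes per-subject 4-D NIfTI
volumes, a brain mask, a ground-truth cluster map, motion traces, and a
`metadata.tsv` (group, PHES, age, education, effect scale).

* **Mask**: ellipsoid at 90% of the half-extents of the grid (default
  30×36×30 voxels of 3 mm; the worked examples use 12³ for speed).
* **Baseline signal**: i.i.d. Gaussian noise band-limited to the
  pass-band and standardized per voxel, so null ReHo reflects only the
  filter-induced autocorrelation.
* **Implanted effect**: inside each spherical `effect_cluster`, the
  affected group's voxel series are mixed with a shared latent series,
  $x = \sqrt{s}\,\ell + \sqrt{1-s}\,\varepsilon$, giving expected
  pairwise correlation $s$ (`strength`, default 0.8) and hence elevated
  KCC; `direction` chooses which group is hyper-synchronous. A
  per-subject `effect_scale` (lognormal-ish, SD 0.25) modulates $s$ to
  create severity variation.
* **Covariates**: PHES is a rounded linear function of the effect
  scale plus noise (group means −7 / −0.6, slope −8, SD 1.2, clamped to
  [−15, 5]), so severity is genuinely coupled to the imaging effect;
  age and education are drawn independently.
* Generation is byte-identical under a fixed `seed`.

The generator emulates the *statistical structure* consumed by the
pipeline: band-limited noise, local synchrony, severity-coupled
covariates, motion traces. It does **not** model hemodynamics,
anatomy, registration, physiological noise, or scanner drift beyond a
linear trend.

## 5. ReliefF feature ranking

`relieff_weights(table, k_neighbors = 1)` is a deterministic full-pass
ReliefF on min-max scaled features: for every subject, find the nearest
same-class subject (near hit) and nearest other-class subject (near
miss) by Euclidean distance in scaled feature space, and update

$$w_f \mathrel{+}= \frac{\mathrm{diff}(f, x, \mathrm{miss}) - \mathrm{diff}(f, x, \mathrm{hit})}{m},$$

with $\mathrm{diff}(f,a,b) = |a_f - b_f| / \mathrm{range}_f$. Defaults
and rationale:

* **k = 1** (single near hit/miss): the cohorts are small (tens of
  subjects), so larger k would average over a substantial fraction of
  the class; k is exposed for larger samples.
* **Full pass** over all subjects rather than random sampling: with
  m ≤ a few dozen a full pass is cheap and removes a randomness source
  from the nested cross-validation.
* **Euclidean metric, min-max scaling**: the standard continuous-data
  instantiation; scaling makes `diff` dimensionless across voxels.

Ties in weights are broken by feature index (`rank_features`), making
the ranking fully deterministic. The test suite pins the exact weights
of a hand-traced 4-subject, 2-feature example.

## 6. Nested leave-one-out classification

`loocv_curve(table, grid, cost = 1)`:

* For each left-out subject, ReliefF is re-run **within the fold** on
  the 19 (or n−1) training subjects only. Ranking once on all subjects
  leaks test information into feature selection and inflates accuracy;
  the leaky variant is available as `rank_on_all = TRUE` strictly for
  comparison, and a structural test asserts the default never sees the
  held-out row.
* For each feature count on the grid (default `feature_grid()` =
  50–5000 by 50, 100 points; grid points above the feature count are
  dropped with a warning), a linear soft-margin SVM (`e1071::svm`,
  C = 1, no internal rescaling) is trained on the top-n training
  features and the held-out subject is predicted. The implementation
  reorders training rows so the +1 class is first, which fixes
  `e1071`'s decision-value sign convention; the primal $(w, b)$ is
  recovered from the support vectors and verified in the tests against
  an independent dual quadratic-program oracle (`kernlab::ipop`).
* Accuracy / sensitivity / specificity are aggregated per grid point;
  `optimal_n` is the **smallest** feature count attaining the maximum
  accuracy (parsimony tie-break).
* The **geometric margin** of each prediction, $d(x)/\lVert w\rVert$,
  is recorded; its Pearson correlation with PHES is the severity
  read-out.

`discriminative_map` projects SVM weights back to the voxel grid.
Default `mode = "consensus"` averages the per-fold weight vectors
voxelwise over the union of their supports, which is more stable than
any single fold; `mode = "single_fold"` reproduces the common practice
of reporting one fold's model (per-fold maps are typically nearly
identical).

**Reported percentages** are rounded half-up to one decimal
(`floor(x·10 + 0.5)/10`), the convention of clinical reports; R's
`round()` rounds half-to-even (81.25 → 81.2), which does not match how
such tables are conventionally printed (81.3).

## 7. Inference

**Permutation test** (`permutation_test`): group labels are permuted,
the *entire* nested LOOCV (including within-fold re-ranking) is re-run
per permutation at a single feature count, and the add-one p-value
$(\#\{A_{perm} \ge A_{obs}\} + 1)/(B + 1)$ is reported. Because LOOCV
accuracy on small samples takes a few discrete values, this p-value is
conservative: over effect-free replicate cohorts the measured rejection
rate at $\alpha = 0.05$ sits below the nominal level (the calibration
test bounds it in [0.01, 0.09]). This is a property of the statistic,
not a defect of the implementation.

**Monte-Carlo cluster-extent threshold**
(`montecarlo_cluster_threshold`): Gaussian white noise on the mask grid
is smoothed to the analysis FWHM, restandardized within the mask,
thresholded at the voxelwise quantile (`voxel_p = 0.01`, one- or
two-sided), and the maximum connected-component size recorded
(26-connectivity by default) over `n_sim` simulations; the threshold is
the smallest size $s$ with $\hat P(\max \ge s) \le \alpha$. Defaults
`voxel_p = 0.01`, `alpha = 0.05`, 26-connectivity follow the AlphaSim
convention for ReHo studies; 6- and 18-connectivity are exposed because
cluster-forming software differs. The FWHM-0 case is checked against an
independent Bernoulli flood-fill oracle.

**Voxelwise correlation** (`voxelwise_correlation`): partial Pearson
correlation between ReHo and PHES controlling age and education
(residualize both against `[1, covariates]`, correlate residuals,
t-test with $df = n - 2 - q$), restricted in `run_pipeline` to the
discriminative-map support within the MHE group, with clusters at or
above the Monte-Carlo threshold retained.

## 8. Problem sizes and runtime

The package's own examples and tests use cohorts of 10–20 subjects per
group on 9³–12³ grids with 40–60 time points — small enough that the
full pipeline (cohort generation → ReHo → nested LOOCV → 100–200
permutations → Monte-Carlo threshold) runs in seconds on one CPU, while
preserving every statistical property of realistic sizes (30×36×30,
160 retained volumes), which the same code handles via the sparse
whole-brain KCC product and vectorized ReliefF.

## 9. Limitations

* The generator validates the pipeline's statistics, not its
  applicability to any particular scanner or population.
* The permutation test's conservatism (Section 7) means borderline
  effects may need more subjects or permutations than the nominal
  $\alpha$ suggests.
* The Monte-Carlo threshold assumes stationary Gaussian smoothness;
  real data may need smoothness estimated from residuals.
* Linear SVM and ReliefF are the only classifier/ranker pair wired
  into `run_pipeline`, though `loocv_curve(ranker = ...)` accepts any
  ranking function.
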
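---
title: "Penalized logistic regression for voxel-pattern diagnosis: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized logistic regression for voxel-pattern diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sglfmri)
```

## The problem and the model

The package classifies subjects into patients (+1) and healthy controls
(−1) from voxel-wise activation Z-scores — one contrast map per subject,
restricted to atlas-labeled voxels and assembled into an `n × d` feature
matrix with `d ≫ n` (the motivating regime is 62 subjects against roughly
14,000 voxels grouped into 105 anatomical areas).

The classifier is the intercept-free logistic model

$$P(y \mid \mathbf{x}; \mathbf{w}) = \frac{1}{1 + \exp(-y\,\mathbf{x}^\top\mathbf{w})},
\qquad y \in \{\pm 1\},$$

fitted by minimizing the penalized negative mean log likelihood

$$J(\mathbf{w}) = f(\mathbf{w}) + \lambda_S \lVert \mathbf{w} \rVert_1
  + \lambda_G \sum_{g=1}^{G} \lVert \mathbf{w}_g \rVert_2,
\qquad f(\mathbf{w}) = -\tfrac1n \sum_i \log P(y_i \mid \mathbf{x}_i; \mathbf{w}),$$

where the groups $g$ are atlas areas. $\lambda_G = 0$ gives the familiar
sparse LASSO (voxel-wise selection), $\lambda_S = 0$ the group LASSO
(area-wise selection), and both positive the sparse-group LASSO. Every
group is weighted equally — there is no $\sqrt{|g|}$ factor in the group
term, which is the literal form of the objective this package implements;
because common group-LASSO practice sometimes includes that factor, an
optional `group_size_weights = TRUE` flag provides it, off by default.

Prediction uses the discriminant rule $\hat y = +1$ iff
$\mathbf{x}^\top\mathbf{w} > 0$. The tie $\mathbf{x}^\top\mathbf{w} = 0$ is
mapped to −1: calling a subject healthy is the conservative resolution of
an exactly uninformative score, and with continuous features the event has
measure zero anyway.

### Why no intercept?

Features are voxel-wise standardized and the designs of interest are
class-balanced, which makes an intercept nearly redundant; omitting it
keeps the fitted model exactly in the form above. An unpenalized intercept
is available behind `intercept = TRUE` for unbalanced data.

## The solver

`sgl_fit()` minimizes $J$ with an accelerated proximal-gradient method
(FISTA) whose inner loop is compiled (RcppArmadillo):

* **Proximal step.** The penalty's proximal operator has a closed form:
  elementwise soft-thresholding by $t\lambda_S$ followed by per-group
  shrinkage by $\max(1 - t\lambda_G/\lVert \mathbf{u}_g \rVert_2,\, 0)$.
  `prox_sgl()` exposes the same operator in R; the test suite certifies it
  against direct numerical minimization of its defining objective.
* **Step size.** Backtracking line search started from the Lipschitz
  estimate $\lVert X \rVert_2^2 / (4n)$ (the logistic loss has curvature at
  most 1/4); the step only shrinks, so the search is cheap after the first
  iterations.
* **Monotonicity.** Plain FISTA is not monotone. If an accelerated step
  increases $J$, the solver falls back to a plain proximal step from the
  current iterate (which cannot increase $J$) and restarts the momentum.
  The recorded objective trace is therefore non-increasing, and
  $J(\mathbf{w}_{\text{final}}) \le J(\mathbf{0}) = \ln 2$ always.
* **Convergence.** Declared when both the relative objective change and the
  relative weight change fall below `tol` (default `1e-8`). The
  `converged` flag is honest: hitting `max_iter` returns a result flagged
  `FALSE` rather than an error, and downstream stability summaries exclude
  such models from their denominators.
* **Support.** A weight counts as selected when $|w_j| >$ `zero_tol`
  (default `1e-8` on standardized features) — below solver resolution,
  numerical dust would otherwise inflate selection counts.
* **Certificates.** `sgl_kkt_violation()` evaluates the exact subgradient
  optimality conditions of the convex objective; tests require violations
  below `1e-5`, and the L1 special case is cross-checked against glmnet.

Along a `sgl_path()` the fits are ordered from strongest to weakest
penalty and warm-started, with the spectral norm computed once. At
$\lambda_S \ge \lVert \nabla f(\mathbf{0}) \rVert_\infty$ (or
$\lambda_G \ge \max_g \lVert \nabla f(\mathbf{0})_g \rVert_2$) the exact
solution is $\mathbf{w} = \mathbf{0}$, which the solver reproduces exactly
from a zero start.

## Preprocessing

The cleaning pipeline is fixed: assemble (atlas-labeled voxels only) →
outlier removal → zero-column removal → voxel-wise standardization →
group construction. Choices that were genuinely open:

* **Outlier granularity.** Entries with $|Z| > 5$ mark artefactual voxels;
  the whole column is dropped for all subjects (keeping the matrix
  rectangular), not just the offending entry. The filter is strict
  ($|Z| = 5$ survives).
* **SD convention.** Standardization uses the sample SD (n−1); recorded in
  the output metadata.
* **Normalization leakage.** The default `"paper"` mode standardizes the
  full matrix before cross-validation, replicating the workflow this
  package models; that choice leaks test-set statistics, so
  `"train-only"` mode (statistics from a designated training subset,
  applied to all rows) is provided and results are labeled by mode.
* **Coordinates.** Voxel coordinates are 0-based `(i, j, k)`; atlas label 0
  means unlabeled and is excluded at assembly.

Two tasks recorded on the same subjects are combined by column
concatenation (`concat_tasks()`); the second task's areas are offset past
the first task's groups, so 105 areas per task yield 210 groups.

## Model selection and evaluation

`nested_cv()` implements nested stratified 10-fold cross-validation:
controls and patients are split separately into folds differing by at most
one subject per class; each outer fold's penalty is chosen by an inner
10-fold cross-validation *on the outer training set only*, maximizing the
mean log likelihood $\mu_{\log L} = \tfrac1n \sum_i \log P(y_i \mid
\mathbf{x}_i)$ of the held-out inner subjects; the model is refitted at
the chosen penalty and the outer fold scored once. The procedure repeats
with reshuffled folds; all randomness derives from one master seed, and
per-fold provenance is recorded so `check_no_leakage()` can audit that
inner selection never saw outer test subjects.

Further choices:

* Inner-fold $\mu_{\log L}$ **pools** all inner-test subjects per grid
  point rather than averaging per-fold means — the pooled form equals the
  criterion over the union and is robust to unequal fold sizes.
* Ties in $\mu_{\log L}$ (within numerical resolution, `1e-9`) break
  toward the sparser model: larger $\lambda_S$, then larger $\lambda_G$;
  ties are flagged in the report.
* Probabilities are clipped at `1e-12` before logs so separable fits stay
  finite.
* Per repeat, metrics come from the pooled confusion counts of all outer
  folds; the report gives mean ± SD over repeats. Because "likelihood" is
  ambiguous as a summary, both $\mu_{\log L}$ and $\exp(\mu_{\log L})$ are
  emitted, explicitly labeled.
* Discriminative scores are the pooled test log odds
  $\mathbf{x}^\top\mathbf{w}$ normalized by the pooled maximum absolute
  value, so they lie in $[-1, 1]$ with the extreme attained exactly once
  up to ties.

The λ grids ship in two presets: `"paper"` (the published grids: 200
log-spaced $\lambda_S$ in [0.01, 0.2512] for sLASSO; 100 $\lambda_G$ in
[0.1, 0.6310] for gLASSO; 20 × 10 combinations over [10⁻⁶, 0.1] ×
[0.0631, 0.3162] for sgLASSO) and `"demo"` (20 points over the same
ranges) for reduced-scale work.

## Stability analysis

`summarize_selection()` aggregates all cross-validated models: per-voxel
selection counts and frequencies, the pooled mean of positive and of
negative selected weights, and per-area rollups (an area counts as
selected when any member voxel is). The pooling order for per-area signed
means was open — per-model-then-average versus pooling all selected
voxel-weights across models — and the pooled form was chosen for its
simplicity and stability at small model counts. Area-level signed means
are additionally normalized by the largest same-sign area mean, and
sign-specific area frequencies are emitted so that areas contributing only
negative (or only positive) weights can be distinguished.
`frequent_set()` applies the strict "> 80 % of models" rule.

## The synthetic-data generator

No subject data ship with the package, so `generate_synth()` provides the
statistical structure the analysis assumes, with known ground truth: a
cuboid pseudo-atlas partitions a toy volume into areas; patients receive a
constant effect on the active-area mask; each patient's mask is
circularly translated by an integer jitter drawn uniformly from
$[-j, j]^3$ (circular, so the active voxel count is constant); all
subjects receive spatially smooth Gaussian noise (FFT-convolved white
noise, rescaled so the marginal SD is exact); and a fraction of entries is
replaced by outliers drawn uniformly from ±[5.5, 8] — safely beyond the
$|Z| > 5$ filter, whose lower edge is all the motivating workflow defines.

### Default conditions, and why

The defaults emulate a 62-subject cohort at reduced scale and were fixed
once, by a pilot calibration of the *regime* rather than of any test
outcome:

| parameter | default | rationale |
|---|---|---|
| `grid_shape` | 10 × 10 × 6 (600 voxels) | large mostly-null voxel space relative to n = 62, the `d ≫ n` regime |
| `n_areas` | 75 (areas of 2×2×2) | area width = 2 × jitter: every affected voxel is unstable across subjects |
| `n_per_class` | 31 | the motivating cohort size |
| `active_areas` | 1–6 | several moderate area-level signals, none individually decisive |
| `effect_size` | 1.5 Z | moderate effect against unit noise |
| `noise_sd` | 1 | Z-score scale |
| `smooth_sigma` | 0.5 voxel | noise correlation length below the area width |
| `jitter_max` | 1 voxel | activity shifted to adjacent voxels between subjects |

Two regime findings from the calibration are worth recording because they
shape what the generator can and cannot show. First, with a rigid
translation of a whole-area mask, the interior of a large area is
perfectly stable under jitter, so voxel-wise selection is never
handicapped there; the jitter-sensitivity the generator exists to emulate
only materializes when the area width is comparable to the jitter.
Second, noise smoothing with correlation length at or above the area
width makes null-area group norms as large as active-area ones (spatially
coherent noise masquerades as a group signal), degrading area-wise
selection for reasons unrelated to the hypothesis under study; the
default keeps the correlation length at half the area width. Under the
defaults, group-penalized models outperform voxel-wise selection by a
comfortable F-score margin across dataset draws, while with
`effect_size = 0` cross-validated accuracy stays at chance.

What the generator does **not** emulate: haemodynamics or time series
(contrast-map level only), realistic anatomical geometry, non-rigid or
subject-specific activation extent, heteroscedastic noise, or site/scanner
effects. Passing tests on synthetic data therefore certify the
*machinery* — solver optimality, selection behavior, accounting — not
clinical performance on real cohorts.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run: solver certificates on
10-dimensional proximal instances and 25 × 6 logistic fits; exact
group-recovery on 50 cohorts of n = 200, d = 400 (20 groups, 3 active,
effect 1.5, noise 1) over the 20-point group-LASSO grid; and nested
10-fold cross-validation (5 shuffled repeats, 20-point grids, solver
tolerance `1e-6` for the selection stage) on the default 62 × 600
conditions. These sizes are the package's reduced-scale defaults; the
`"paper"` grid preset and larger specs scale the same code up.

## Cohort-table statistics

`t_test_from_summary()` reproduces two-sample t-tests from printed
summaries (n, mean, SD) alone. The pooled-variance variant is the default
because it exactly reproduces the published semantic-task p-values from
the printed summaries; Welch is reported alongside (with equal group
sizes the statistics coincide and only the degrees of freedom differ).
`chi2_2x2()` delegates to the standard Pearson chi-square. A caveat
documented rather than hidden: the phonological-task rows of the bundled
table do not reproduce their published p-values from the rounded
summaries (the source's own text and table even disagree on one SD at the
second decimal), so those two rows are computed and reported but carry no
expectation of matching.

## Known limitations

* FISTA at desk scale; no coordinate descent, screening rules, or sparse
  matrix paths. Adequate for `d` in the tens of thousands, not millions.
* The `"paper"` normalization mode leaks test statistics by construction
  (provided for fidelity; `"train-only"` is the clean alternative).
* Sign-specific area frequencies follow the natural counting rule (an
  area counts for a sign in a model if any member voxel is selected with
  that sign); other conventions exist.
* The generator's jitter is a rigid translation; real inter-subject
  variability also deforms and rescales activation.
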
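# sglfmri

Sparse, group and sparse-group LASSO logistic regression for diagnostic
classification from voxel-wise brain activation maps.

## What problem this solves

In multi-voxel pattern analysis (MVPA) of task fMRI, one wants to predict a
subject's diagnosis — e.g. major depressive disorder versus healthy control —
from a per-subject contrast map of activation Z-scores, with tens of subjects
against tens of thousands of voxels. Plain L1 (LASSO) logistic regression
handles `d ≫ n` but selects isolated voxels, which is fragile when activity
shifts to adjacent voxels between subjects. Grouping voxels by anatomical
atlas areas and penalizing whole groups yields classifiers that select brain
*areas*, which are both more robust and more interpretable.

The package is aimed at neuroimaging methodologists and students who need a
complete, auditable implementation of this pipeline: the penalized model, a
certified solver, leakage-free nested cross-validation, probabilistic
scoring, and stability analysis of what gets selected — plus a synthetic
cohort generator with known ground truth, so everything is testable without
any subject data.

## The model

For features `x ∈ ℝ^d` (voxel Z-scores) and label `y ∈ {±1}` (+1 = patient),

    P(y | x; w) = 1 / (1 + exp(−y xᵀw))

with weights chosen to minimize

    J(w) = f(w) + λ_S ‖w‖₁ + λ_G Σ_g ‖w_g‖₂ ,
    f(w) = −(1/n) Σ_i log P(y_i | x_i; w)

over atlas-area groups `g = 1..G`. `λ_G = 0` is the sparse LASSO, `λ_S = 0`
the group LASSO, both positive the sparse-group LASSO. The solver is a
monotone FISTA (accelerated proximal gradient with backtracking and a
descent safeguard) with a compiled core; optimality is certified in the test
suite by KKT subgradient conditions, a numerical prox oracle, and a glmnet
cross-check of the L1 special case. Penalties are selected by nested
stratified 10-fold cross-validation maximizing the held-out mean log
likelihood `μ_logL = (1/n) Σ log P(y_i | x_i; w)`.

## Worked example

```r
library(sglfmri)

# a synthetic 62-subject cohort: 600 voxels, 75 areas, 6 carrying a
# jittered class effect (the package defaults)
ds <- generate_synth(synth_spec(seed = 1))
pp <- preprocess_pipeline(ds$features)

fit <- sgl_fit(pp$features$values, pp$features$labels, pp$groups,
               penalty_config(lambda_s = 0, lambda_g = 0.3))
print(fit)
#> sgl_fit: lambda_s=0 lambda_g=0.3 | J=0.6388 | 24/600 nonzero weights in 3 groups | converged in 78 iter

rep <- nested_cv(pp$features$values, pp$features$labels, pp$groups,
                 lambda_grid("glasso", "demo"), n_repeats = 5, seed = 1,
                 tol = 1e-6)
print(rep)
#> cv_report: 5 repeats of nested 10-fold CV on 62 subjects
#>   sensitivity  0.8258 +/- 0.0177
#>   specificity  0.8968 +/- 0.0270
#>   accuracy     0.8613 +/- 0.0088
#>   precision    0.8897 +/- 0.0246
#>   recall       0.8258 +/- 0.0177
#>   fscore       0.8562 +/- 0.0079
#>   mu_logL      -0.3394 +/- 0.0151
#>   likelihood   0.7123 +/- 0.0107

stab <- summarize_selection(rep, pp$groups)
print(stab)
#> selection_summary over 50 models (0 excluded as non-converged)
#>   #selected voxels per model: 78.56 +/- 11.84
#>   #voxels (#areas) selected at least once: 192 (24)
#>   max occurrence of same voxel: 100.0%
#>   #voxels with > 80% occurrence: 56
frequent_set(stab, 0.8, "area")$name
#> [1] "synthetic-A:6"  "synthetic-A:2"  "synthetic-A:5"  "synthetic-A:4"
#> [5] "synthetic-A:47" "synthetic-A:10" "synthetic-A:52"
```

Reading the output: the nested CV classifies the synthetic cohort at about
86 % accuracy (mean ± SD over 5 shuffled repeats of the full nested
procedure); `likelihood` is `exp(μ_logL)`. The stability summary pools the
5 × 10 refitted outer-fold models: each kept ~79 voxels, and the areas
selected in more than 80 % of models are dominated by truly active areas
(1–6 in this cohort) plus jitter-spillover neighbours. Per-subject
normalized discriminative scores (log odds normalized by the pooled
maximum, in [−1, 1]) are in `rep$scores`.

Cohort-table statistics from printed summaries:

```r
t_test_from_summary(group_summary(31, 29.19, 1.51),
                    group_summary(31, 27.81, 3.12))$p   # 0.0304
chi2_2x2(15, 16, 16, 15, correction = "none")$p         # 0.799
```

## Package layout

- `R/synthetic_data.R` — pseudo-atlas and cohort generator with ground truth
- `R/preprocess.R` — assembly, outlier/zero-column filters, standardization,
  task concatenation, group construction
- `R/sglasso.R`, `src/sgl_fista.cpp` — penalty, prox, monotone FISTA solver,
  regularization path, KKT certificate
- `R/evaluation.R` — λ grids, stratified folds, nested CV, metrics,
  discriminative scores, leakage audit
- `R/stability.R` — selection frequencies, >80 % rule, volume weight maps
- `R/cohort_stats.R` — t-tests from summaries, 2×2 chi-square
- `R/pipeline.R` — end-to-end orchestration with config hashing and logging
- `vignettes/methods.Rmd` — models, numerics and design decisions
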
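# mrifusion

Classification toolkits for early diagnosis and prognosis of Alzheimer's
disease from structural brain MRI, implemented in R and exercised end to
end on synthetic brain-like cohorts.

## The problem

Given gray-matter probability volumes co-registered to a common template
space and a binary diagnostic contrast (AD vs. CN, or MCI converters
vs. non-converters), the package implements two complementary
classification strategies and the evaluation machinery around them:

* **Method #1 — fusion of two conventional-ML pipelines.** Flattened voxel
  features are reduced either by *Aggregate Selection* — Fisher score,
  two-sample t statistic and sparse L1-logistic importances combined
  through analytic-hierarchy-process comparison matrices
  (`M_ij = s_i/s_j`, principal eigenvector per criterion, performance
  matrix × weight vector, `CI = (λmax − n)/(n − 1)`, `CR = CI/RI`) — or by
  *kernel PLS* (components from the leading eigenvector of `K_X K_y` with
  kernel deflation, feature weights
  `w_i = D · Σ_l Ψ(Y,t_l) v_il² / Σ_l Ψ(Y,t_l)`), then classified by a
  linear SVM with Platt-scaled outputs; the two SVM score vectors are
  fused by the sum rule.
* **Method #2 — per-slice 2D ensembles.** The 3D volume is decomposed into
  RGB-like 2D images (bands = slices `n`, `n+gap`, `n+2·gap`; approaches
  A/B/C/D = sagittal/coronal/transaxial/mixed; `gap ∈ {0,1,2}`). One 2D
  model is trained per `(approach, gap, n)` slice group across subjects,
  and scores are sum-rule fused bottom-up: slices → configuration →
  backend.
* A **patch-based 3D CNN** trained from scratch (conv → ReLU → max-pool →
  FC → soft-max; non-overlapping patches, per-volume score = sum-rule merge
  of patch scores; SGDM, initial learning rate 1e-4).
* **Nested cross-validation** with AUC (Mann–Whitney, ½-tie convention),
  instrumented against train/test leakage, plus a paired whole-volume
  vs. inner-structures (100-central-slice crop) comparison.
* A **synthetic cohort generator** (NIfTI-1 out): smooth template + subject
  noise + class-dependent localized intensity reduction emulating atrophy,
  so that every stage is testable without restricted clinical data.

See `vignettes/mrifusion-methods.Rmd` for the full model description,
parameter meanings and design decisions.

## Worked example

Simulate a co-registered cohort with an inner-localized atrophy-like
effect, evaluate Method #1 by nested cross-validation, and compare regions:

```r
library(mrifusion)

spec <- synth_spec(shape = c(20, 24, 20), n_per_class = 10,
                   d = 0.35, region = "inner", noise_sd = 0.1, seed = 42)
cohort <- make_cohort(spec)

plan <- cv_plan(k_out = 5, k_in = 2, grid = list(C = c(0.1, 1)), seed = 42)
res <- run_nested_cv(cohort, method1_builder(as_k = 50, kpls_h = 4), plan)
res
#> <cv_result> AUC = 1.000 over 5 folds (n = 20)

cmp <- compare_regions(cohort,
                       function(ck) method1_builder(as_k = 50, kpls_h = 4,
                                                    crop_k = ck),
                       plan, crop_k = 16)
round(c(whole = cmp$whole$auc, inner = cmp$inner$auc, diff = cmp$auc_diff), 3)
#> whole inner  diff
#>     1     1     0
```

The out-of-fold AUC of 1.0 reflects the strong simulated effect (35%
intensity reduction in the inner region at noise sd 0.1): feature selection
localizes the affected voxels and the fused SVMs separate the classes
perfectly; with `d = 0` the same pipeline stays at chance (see the
null-calibration tests). Decomposition works the same way from the shell:

```sh
Rscript inst/cli/mrifusion.R simulate --out /tmp/demo --shape 20x24x20 --n 10 --seed 1
Rscript inst/cli/mrifusion.R decompose --volume /tmp/demo/sub-001.nii.gz --approach A --gap 1
#> 6 RGB-like images (approach A, gap 1)
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's analytic acceptance
quantity from scratch — it builds a pairwise comparison matrix from a
random strictly positive score vector (order 3–10, drawn from `--seed`),
computes the principal eigenvalue, consistency index and consistency
ratio, and writes the result as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
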
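---
title: "Methods: slice-decomposition ensembles and feature reduction for brain MRI classification"
author: "mrifusion authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slice-decomposition ensembles and feature reduction for brain MRI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrifusion)
```

## The problem

Early diagnosis and prognosis of Alzheimer's disease from structural brain
MRI is usually cast as a set of binary classification tasks: patients versus
cognitively normal controls (AD vs. CN), and — clinically most relevant —
mild-cognitive-impairment patients who later convert to dementia versus
those who do not (MCIc vs. MCInc). The input is a gray-matter probability
volume, already co-registered to a common template space so that a voxel
index means the same anatomical location in every subject. `mrifusion`
implements, in R, a complete toolkit for these tasks:

* a conventional machine-learning branch — voxel features reduced by
  **Aggregate Selection** or **kernel partial least squares**, classified by
  a linear **SVM**, with the two pipelines fused by the sum rule
  ("Method #1");
* a slice-ensemble branch — the 3D volume decomposed into **RGB-like 2D
  images** (three slices per image) feeding per-slice 2D classifiers whose
  scores are fused across slices, decomposition approaches, gaps and
  backends ("Method #2");
* a **patch-based 3D convolutional network** trained from scratch;
* a **nested cross-validation** harness with AUC evaluation and a paired
  whole-volume versus inner-structures comparison;
* a **synthetic cohort generator**, because the clinical repositories the
  method family was developed on are access-restricted. Every pipeline
  stage is exercised end to end on synthetic brain-like volumes.

## Volumes and cropping

A volume is a finite 3D grid with axis order sagittal × coronal ×
transaxial (RAS). The reference geometry after template registration is
121 × 145 × 121 voxels. `crop_inner()` keeps the `k = 100` central slices of
each axis, yielding the 100³ "inner cerebral structures" region that
includes the hippocampus. The centering rule is `start = floor((extent -
k)/2)` per axis, dropping the extra voxel (odd differences) on the
high-index side; nothing is interpolated. `k` is configurable so that small
synthetic volumes exercise the same code path.

NIfTI-1 I/O is implemented directly (348-byte header, float32 data,
plain or gzip): no NIfTI reader is available in the dependency set, and the
format subset needed here — single-file scalar volumes in a common space —
is small. Volumes written by the package carry an identity sform and the
registration-space tag in the header `descrip` field; `read_cohort()`
enforces that all volumes of a cohort share shape and space tag.

## RGB-like decomposition

2D convolutional networks expect 3-channel images; MRI volumes are
1-channel 3D grids. The bridge is to stack three slices as the R, G and B
bands of one 2D image. Four approaches are supported — A (three sagittal
slices), B (coronal), C (transaxial), D (one slice of each orientation) —
with band indices `n`, `n + gap`, `n + 2·gap`. `gap` is the slice distance
between bands (`gap = 1` means adjacent slices, `gap = 0` three identical
bands). Anchors run from the first slice while all three bands fit.

Two points were left open by the source material and decided here:

* **Stride between anchors.** The images of one volume should "compose" it
  without an explicit step size being stated. Default: stride 1 for
  `gap = 0` and `2·gap + 1` for `gap > 0`, i.e. consecutive images use
  non-overlapping slice triplets. The stride is configurable; overlapping
  anchors (`stride = 1`) are supported.
* **Approach D on non-cubic volumes.** The three orientations give planes
  of different shapes; bands are zero-padded symmetrically to the
  element-wise maximum shape (a no-op on the cubic 100³ crop). Padding
  preserves spatial content without interpolation; resizing would blur the
  co-registration guarantee.

Intensities are min–max scaled to [0, 1] per volume before composition
(once per volume), so backends see bounded inputs; this is recorded in the
configuration. Resizing to a backend's native input size is the backend's
responsibility, not the decomposition's.

Because the cohort is co-registered, the image of subject X centered on
slice `n` is anatomically comparable to the image of subject Y centered on
the same `n`: per-slice models are therefore trained strictly within one
`(approach, gap, n)` group (`group_by_slice()` enforces this), and a model
never sees images from other keys.

## Aggregate Selection

Three ranking criteria are computed per voxel feature: the Fisher score,
the absolute Welch two-sample t statistic, and the absolute coefficients of
an L1-penalized logistic regression (sparse; most scores exactly zero at an
adequate penalty — fit with `glmnet` coordinate descent, penalty chosen by
inner cross-validation). Their raw statistics live on incommensurate
scales, so rankings are made comparable through the analytic hierarchy
process: scores `s` become a pairwise comparison matrix `M_ij = s_i / s_j`,
and the normalized principal eigenvector of `M` — which for a ratio matrix
is exactly `s / sum(s)` — forms one column of a performance matrix. The
final ranking is the performance matrix times the criterion weight vector
(equal weights 1/3 by default, set a priori to avoid bias), and the top `k`
features are kept (ties broken by stable feature order).

Design choices worth knowing:

* Ratio matrices are transitive and perfectly consistent by construction:
  the principal eigenvalue equals the order `n`, so `CI = (λmax − n)/(n −
  1) = 0` and `CR = CI/RI = 0`. This is the only construction that scales
  to `D` in the tens of thousands, where elicited pairwise judgments are
  impossible; the closed form `s / sum(s)` is used internally and its
  equality with the dense eigensolver is property-tested.
  `build_comparison_matrix()` / `consistency_ratio()` expose the full
  machinery (eigenpair, CI, CR, Saaty's random-index table for `n ≤ 15`,
  `1.98 (n − 2)/n` beyond) for explicit matrices.
* Scores are positivized before ratio construction by shift-and-floor
  (`s − min(s) + 10⁻⁶·range(s)`) when non-positive values occur; already
  strictly positive vectors pass through unchanged.
* Degenerate ratios follow a fixed convention: zero between-class spread
  over zero variance scores 0; a perfect separator with zero within-class
  variance gets the largest finite score plus one.
* A criterion whose scores are all equal (e.g. the sparse logistic under a
  penalty that zeroes every coefficient) carries no ranking information and
  contributes the uniform column instead of an error.

## Kernel PLS

Components are extracted in a kernel-induced feature space: on the current
(deflated) kernels, the component is the leading eigenvector of `K_X K_y`
(`K_y = y_c y_cᵀ` on the centered label vector) — the fixed point of the
kernel-NIPALS iteration — after which both kernels are deflated by
projection off the component. Ten components are the reference default;
when the residual label kernel is numerically exhausted earlier, the model
returns the achievable components with a warning (a common situation at
desk-scale N). Since the label kernel has rank one, the power iteration
converges in a couple of steps.

Per-feature explanatory weights aggregate squared correlation loadings
(`v_il` = Pearson correlation of feature `i` with component `l`) across
components, weighted by the component–label correlation `Ψ(y, t_l)`; each
component is sign-oriented so that it correlates non-negatively with the
class-1 indicator, which keeps the weights non-negative. The component
contribution `γ_l` is the class-size-weighted mean of the class means of
the component scores, evaluated exactly as stated; note that on centered
components this weighted grand mean is ~0 by construction — it is exposed
as a diagnostic, together with the between/within-class scatter matrices
(`S1`, `S2`) and the discriminative projection `α` of the component scores.

The default kernel is Gaussian with the median-pairwise-distance bandwidth
heuristic; a linear kernel is available and is what the oracle tests use
(at `h = 1` the component provably matches classical primal NIPALS PLS).
Out-of-sample projection uses the standard kernel-PLS formula
`T_new = K_new_centered · U (Tᵀ K U)⁻¹`, which reproduces the training
components exactly on the training set.

## Classifiers

**SVM.** No SVM implementation exists in the dependency set, so the package
carries a linear L2-regularized hinge-loss SVM solved in the dual by
coordinate descent (the standard dual CD scheme; bias as a constant
feature; deterministic sweep order derived from the seed). A linear kernel
is the appropriate default with voxel features vastly outnumbering
subjects. Decision values are mapped to [0, 1] by Platt scaling
(regularized-target Newton fit), so that sum-rule fusion always operates on
commensurate probability-style scores. The cost `C` is the one
hyperparameter exposed to the nested-CV grid (default `{0.01, 0.1, 1,
10}`).

**Slice backends.** Per-slice 2D models implement one contract:
`train(X, y, seed)` returning a scorer mapping flattened band matrices to
[0, 1]. The desk backend (`"lin"`) is a regularized linear discriminant on
standardized flattened bands with Platt-scaled outputs — deterministic and
fast enough for hundreds of per-slice models inside cross-validation; a
ridge-logistic and a linear-SVM backend are also provided, and
fine-tuned pretrained networks would slot behind the same interface
(distributing ImageNet weights is out of scope; the reference training
hyperparameters — learning rate 10⁻⁴, mini-batch 30, convergence within a
20-epoch cap — are recorded in the backend spec). Swapping backends changes
scores but not pipeline structure, which is interface-conformance tested.

**3D CNN.** The fixed layer sequence is convolution → ReLU → max-pool →
fully-connected → soft-max → classification. Volumes are tiled into
non-overlapping patches (reference 28 × 28 × 121, conv and pool stride 4;
the 121 × 145 × 121 volume yields 4·5·1 = 20 patches; leftover margins
beyond the last full patch are dropped, grid anchored at the first voxel).
Each patch inherits its parent volume's label; one network is trained on
all patches by stochastic gradient descent with momentum (0.9) at initial
learning rate 10⁻⁴, and a volume's score is the sum-rule merge of its patch
scores. The convolution is realized as a linear map over a precomputed
im2col expansion, making forward and backward passes plain matrix algebra —
appropriate for desk-scale geometries (the full-scale reference
configuration is supported but not exercised in tests). Desk-scale test
runs use a reduced geometry (8 × 8 × 16 patches, 4 filters) and a learning
rate of 10⁻³ over 100 epochs, chosen once as the smallest budget at which
training reliably converges at that scale; the reference defaults are
untouched.

## Sum-rule fusion

The sum rule is realized as the unweighted mean of member scores — AUC is
identical under sum and mean, and the mean keeps fused scores in [0, 1] at
every tree level. Fusion is applied bottom-up: slices → (approach, gap)
configuration → backend (Method #2); or across the AS+SVM and kPLS+SVM
pipelines (Method #1). Members must score the same subject set; fused AUC
is invariant under a common strictly increasing transform only for a single
member, which is why all members are calibrated to [0, 1] before summation
(the source material does not state whether soft-max and SVM outputs were
normalized before fusion; calibration is this package's choice).

## Evaluation

`auc()` implements the Mann–Whitney form (probability that a random
positive outscores a random negative, ties counted ½ via mid-ranks).
`run_nested_cv()` embeds *all* fitting — feature reduction, hyperparameter
choice, model training — inside each outer training fold; the inner loop
(default 5 folds, stratified) selects hyperparameters by inner AUC. Outer
folds default to 10, matching the validation style of the source cohort
studies; both are configurable. The harness logs the subject ids of every
fitting call, so the absence of leakage is a hard, testable assertion
rather than a convention. All fold assignments and training seeds derive
from the plan seed; two runs with the same seed are bit-identical on one
thread. `compare_regions()` runs whole-volume and inner-crop evaluations
under identical fold assignments (paired design).

No multiple-testing correction is applied anywhere (none is part of the
replicated procedure); across-method comparisons are descriptive AUC
differences.

## Synthetic cohorts

`make_cohort()` draws a smooth template (superposed smoothed blobs, edge-
renormalized separable Gaussian smoothing, rescaled to [0, 1]) shared by
all subjects, then adds per-subject lightly-smoothed Gaussian noise
(sd 0.1 by default). Class 1 scales the template inside the affected
region by `(1 − d)` before noise — a localized intensity reduction
emulating gray-matter atrophy. The default region is the central-crop
window (`inner_k = floor(min(shape)·100/121)`, the same proportion as the
100-of-121 reference crop), so the whole-volume versus inner-structures
experiment mirrors by construction the clinical expectation that inner
structures are affected earliest. `d = 0` makes the classes exchangeable
(null calibration); `d = 0.3` at the default noise is a strong, easily
recoverable effect (power calibration). The default cohort is 20 + 20
subjects of 40 × 48 × 40 voxels — large enough for stable folds, small
enough for minutes-scale nested CV on one CPU; the full 121 × 145 × 121
geometry is supported.

What the generator deliberately does **not** emulate: neuroanatomy, scanner
artifacts and inhomogeneities, multi-site resolution differences,
registration error, longitudinal change. A green test on synthetic cohorts
establishes that the pipeline machinery is correct and calibrated — not
that clinical AUC levels are reproduced; the headline clinical numbers were
obtained on restricted repositories and are out of scope here.

## Numerical conventions

* Comparison-matrix consistency: `CR` snaps to 0 when `CI < 10⁻¹²`
  (machine-level consistency); `RI` from Saaty's table (`n ≤ 15`), else the
  asymptotic approximation.
* kPLS deflation stops (with a warning) when the deflated `K_X K_y` norm
  falls below 10⁻¹⁰ of its initial value.
* Platt scaling uses regularized targets and Newton steps with
  backtracking; degenerate projections (zero variance) fall back to the
  class prevalence.
* Ties in all rankings break by stable feature order; `max.col` pooling
  argmax uses `ties.method = "first"`.
* All stochastic steps take explicit seeds; library code never perturbs the
  caller's RNG state (seeds are scoped and restored).

## Known limitations

* The sparse-logistic criterion stands in for the original Bayesian-L1
  formulation: coordinate-descent L1 logistic with CV-chosen penalty, not
  the exact hyperpriors of the original reference.
* Fine-tuning real pretrained 2D architectures is out of scope at desk
  scale; the backend interface is where such models would plug in.
* Multiclass (> 2) tasks, DICOM input, registration/segmentation
  preprocessing, weighted or trainable fusion, and DeLong confidence
  intervals are out of scope.
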
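---
title: "Stratifying cognitive decline on the Alzheimer's continuum from AT(N) biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying cognitive decline on the Alzheimer's continuum from AT(N) biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Individuals on the Alzheimer's disease continuum decline at markedly
different rates. `atnprog` implements a two-stage, model-based stratification
of that heterogeneity:

1. **Data-driven phenotyping.** Longitudinal cognitive scores (MMSE-like,
   four visits over 24 months) are clustered with a dynamic-time-warping
   (DTW) dissimilarity and hierarchical agglomerative clustering into
   *moderate decliners* (MD) and *fast decliners* (FD). Silhouette analysis
   selects the number of clusters.
2. **Prognosis from baseline biology.** A parameter-efficient multimodal 3D
   convolutional network (PENet) predicts the phenotype from *baseline*
   AT(N) biomarkers: CSF amyloid-beta (A), CSF p-tau (T), and
   neurodegeneration (N: a structural volume plus an FDG-PET composite).
   An ablation harness retrains the same network on biomarker subsets —
   N, A(N), T(N), AT(N) — under identical folds and seeds, so accuracy
   differences measure the prognostic value that each biomarker adds,
   including non-additive amyloid-by-tau synergy.

A third, descriptive stage relates the phenotypes to atrophy-based disease
subtypes defined by the hippocampal-to-cortical volume ratio.

Because the motivating cohort data are access-restricted, the package ships
a synthetic-cohort generator that reproduces the *statistical structure*
the analysis assumes, making every stage testable end to end.

# The synthetic cohort generator

`cohort_config()` / `generate_cohort()` draw, per subject: a cognitive
trajectory, a phantom 3D volume, baseline scalar biomarkers (CSF
amyloid-beta and p-tau in pg/mL, an FDG composite, amyloid-PET SUVR, and
intracranial volume in mm^3), regional volumes, and demographics.

**Trajectories** follow `score(t) = baseline + slope * t + nonlinearity *
t^2 + noise` with `t` in years and visits at months 0, 6, 12, 24 (the
default reading of "four time points during 24 months"; the grid is
configurable). Default class parameters — MD: baseline 27, slope −1.2/yr;
FD: baseline 25.5, slope −4.5/yr, stronger curvature; visit noise sd 1 —
were calibrated once so that the qualitative picture of two separating
trajectory bundles over 24 months emerges, and are all overridable.

**Volumes** are piecewise-constant phantoms: a cortex-like ellipsoidal
shell and two hippocampus-like ellipsoids on zero-mean Gaussian background
noise, with the region intensities scaled by per-class atrophy factors.
This gives the volume encoder class-informative spatial signal without
pretending anatomical realism. Note one consequence: volumes are z-scored
per image before entering the network, so a *global* intensity scaling is
removed by standardisation — the discriminative phantom signal is the
hippocampus-to-cortex contrast ratio and the signal-to-background contrast,
which is exactly what the class-specific atrophy factors modulate.

**Synergy mode.** With `synergy_coefficient != 0` (the
`synergy_cohort_config()` preset uses 2), class labels are drawn from a
logistic model on independent standard latents:
`logit P(FD) = b0 + 0.5 z_A + 1.1 z_T + 1.0 z_N + gamma z_A z_T`.
Observed amyloid and tau are exact affine readouts of `z_A`, `z_T`
(pathological direction: low amyloid-beta, high p-tau); the FDG composite
is a noisy readout of `z_N` (correlation 0.75), and the phantom atrophy
factors track `z_N`. Under this design the Bayes-optimal accuracy is
ordered AT(N) > T(N) > N with several points between steps, so the joint
AT(N) information genuinely exceeds every marginal subset — the property
the ablation harness is meant to detect. In synergy mode the requested
class proportions only steer the intercept; realised counts are random.

Clamping keeps concentrations, volumes and scores physical (non-negative;
scores in [0, 30]); with the default parameters clamping is rare and the
logistic refit of the labels on the latents recovers the synergy
coefficient within its confidence interval (this is a frozen test).

What the generator does *not* emulate: scanner and sequence effects,
spatial covariance of real atrophy, measurement drift, missing visits and
informative dropout, and realistic biomarker correlation structure beyond
the latent model above. Passing tests therefore demonstrate that the
*pipeline* behaves as specified under its assumptions, not that the
reported effect sizes transfer to clinical data.

# Trajectory clustering choices

* **DTW cost.** Classic dynamic program, local cost `|a_i - b_j|`, steps
  {(1,0), (0,1), (1,1)}, no warping window and no path-length
  normalisation. Absolute (not squared) cost is robust for 4-point series;
  both the cost and the absence of a window are deliberate, documented
  choices for short clinical series.
* **Raw scale.** Scores are clustered on their native scale — the baseline
  offset is part of the phenotype signal — so no z-scoring before DTW.
* **Linkages.** `ward2` (Ward on squared dissimilarities, heights reported
  on the original scale), `ward1` (Ward recursion on the dissimilarities as
  given) and UPGMA, all via Lance–Williams updates. Ties in the minimum
  merge distance break toward the lexicographically smallest cluster pair,
  which makes trees platform-independent.
* **Missing visits** drop the subject from clustering (with a warning); no
  imputation.
* **Naming.** In a 2-cluster solution the cluster with the more negative
  mean least-squares slope is FD; exact ties break toward the larger
  baseline mean being MD.

# Post-clustering statistics

Comparing the clusters on the very scores that produced them inflates
type-I error. Instead of a selective-inference procedure, the package uses
a *pipeline-honest permutation test* (`permutation_cluster_test()`): the
statistic is the DTW distance between cluster mean trajectories, and each
null replicate rebuilds a label-free dataset (grand-mean trajectory plus
column-wise independently permuted residuals), re-runs the complete
cluster-then-compute pipeline on it, and recomputes the statistic. The
column permutation destroys both cluster structure and residual
autocorrelation, so the test is exact only when residuals are independent
across visits — true of the bundled generator, and approximately true of
visit-level measurement noise; strong within-subject correlation in real
data would make it anticonservative. This substitution is a methodological
stand-in and is labelled as such.

The repeated-measures ANOVA (`rm_anova()`) is the classical two-way
mixed design (between = phenotype, within = visit) on a complete balanced
panel, reported as `F(t-1, (n-g)(t-1))` without sphericity correction by
default; a Greenhouse–Geisser option exists. The chi-square test uses no
continuity correction by default. Group comparisons are Welch t or
Wilcoxon rank-sum tests.

# PENet: architecture and training

The volume encoder uses **2 convolution blocks followed by 3
depthwise-separable convolution blocks** with strictly increasing filter
counts; each block is convolution, batch normalisation, ELU. A separable
block (depthwise `k^3` filter per channel, then a pointwise 1×1×1
convolution) costs `k^3 C_in + C_in C_out + C_out` parameters against
`k^3 C_in C_out + C_out` for a full convolution — the parameter efficiency
that motivates the design. Each enabled scalar biomarker passes through its
own small fully-connected branch; volume features and branch outputs are
concatenated and classified by fully-connected fusion layers with a 2-class
softmax. Forward and backward passes are implemented in the package
(Rcpp/Armadillo im2col convolutions; batch-norm, ELU, dense layers and SGD
in R), single-threaded and bit-reproducible given a seed.

`train_config()` keeps the reference regime: SGD, batch 25, 50 epochs,
initial learning rate 8e-4 with exponential decay (rate 0.5; the decay
period is not pinned by the reference regime — default one drop per 10
epochs), and L2 penalty 5e-4 on fully-connected weights. Inputs are
standardised: volumes z-scored per image, scalars z-scored with
*training-fold* statistics only (the transform record is kept, and a guard
prevents double application).

**Desk-scale presets.** The experiments in this package run on one CPU, so
`desk_penet_spec()` (filters 4/8 + 12/16/24, 16^3 input; phantoms are
resampled trilinearly to the encoder input shape) and
`desk_train_config()` (10 epochs, learning rate 0.1 with decay period 4,
no augmentation copies) define the problem sizes used by the bundled
experiments and the acceptance script: ablations on n = 200 synergy
cohorts with 32^3 phantoms, 5-fold stratified CV, 10 seeds. At roughly 70
SGD updates per fold the GPU-scale learning rate of 8e-4 cannot move the
weights appreciably; 0.1 with batch normalisation is stable and was chosen
as the desk default alongside the other preset values.

**Augmentation** applies axial-plane rotation (angle uniform in
[−90°, 90°]), per-axis translation (fraction uniform in [0, 0.5], random
direction) and coin-flip mirroring, filling exposed voxels with the
background value; nearest-neighbour interpolation by default so the
zero-parameter augmentation is bitwise the identity. Augmented copies are
created *within* each training fold only — the only leakage-safe reading —
and a guard asserts every fold that no tensor from a held-out subject
(original or augmented) enters fitting.

**Loss and folds.** Two-class cross-entropy without class weighting;
stratified k-fold CV balances class counts per fold within one subject.
Fold assignment, weight initialisation, shuffling and augmentation draws
all derive from the configured seed via `derive_seed()` (a keyed hash per
stage name), so identical configurations reproduce identical metrics.

# The ablation harness

`run_ablation()` retrains the same specification per biomarker combination
(N = MRI + FDG; A(N); T(N); AT(N); N + ICV; MRI-only; N + noise probe)
with *identical folds and seeds* — a paired design, so input content is
the only varying factor. It reports fold-accuracy mean ± sd, pooled
out-of-fold accuracy and pooled AUC (both views are reported because
either summary convention is defensible), and full ROC points. AUC uses
the Mann–Whitney form with ties counted one half; the ROC trapezoid equals
it identically, which is a frozen test. DeLong inference (placement-value
covariances) supports both a single-model test against chance (0.5) and
paired model comparisons. Baselines: cross-validated logistic regression
and an RBF-kernel SVM under the same folds; since no reference describes
how 3D volumes feed an SVM, `svm_imaging_features()` uses a downsampled
(8^3) standardised volume plus the FDG scalar, and this is documented as
an assumption. Multiple-comparison correction across ablation cells is
off by default (a Holm option is available via `p.adjust`).

# Atrophy subtypes

`assign_subtypes()` cuts the HV:CTV ratio at its within-sample 25th/75th
percentiles (linear-interpolation percentile definition, `quantile`
type 7): above the 75th percentile is hippocampal-sparing, below the 25th
limbic-predominant, the rest typical AD. Inequalities are strict, so
boundary-equal subjects fall to typical AD; external reference thresholds
can be supplied. Voxel-based morphometry contrasts are out of scope; the
phantom cohort instead supports per-region mean-difference summaries.

# Numerical and degenerate-input choices

* Exact merge-distance ties: lowest cluster-index pair first.
* Silhouette of singleton clusters is 0; an all-zero dissimilarity matrix
  is a degenerate-silhouette error.
* All-equal scores give F = 0 (not NaN) in the ANOVA.
* Identical score vectors give z = 0, p = 1 in the DeLong test.
* Zero-variance features are dropped (with a warning) by standardisation
  and the scalar baselines.
* Biomarker draws are clamped to stay positive; trajectory scores to
  [0, 30].
* Divergent training (non-finite loss) raises an error carrying the
  learning rate and seed.

# Known limitations

* The permutation test's validity rests on visit-independent residuals
  (see above).
* Phantom volumes exercise the encoder but cannot validate anatomical
  claims; desk-scale accuracies quantify the *ordering* of biomarker
  combinations under the generator's assumptions, not clinically
  attainable performance.
* The PENet implementation favours clarity and reproducibility over
  throughput; it is single-threaded and CPU-bound by design.
* Secondary cognitive panels are affine readouts of the same latent
  decline, adequate for exercising the repeated-measures machinery only.
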
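# atnprog

Model-based stratification of progression along the Alzheimer's disease
continuum, for researchers studying heterogeneity of cognitive decline and
the prognostic value of baseline biomarkers.

Individuals with prodromal or clinical Alzheimer's disease decline at very
different rates. `atnprog` implements a complete, reproducible pipeline
around that observation:

1. **Progression phenotyping.** Longitudinal cognitive scores (four visits
   over 24 months) are compared with dynamic time warping
   (cost `|a_i − b_j|`, unconstrained global alignment) and clustered by
   hierarchical agglomeration (Ward's `ward2`/`ward1` and UPGMA linkages,
   Lance–Williams updates, deterministic tie-breaks). Silhouette analysis
   selects the number of clusters; the two-cluster solution is named
   *moderate decliners* (MD) and *fast decliners* (FD) by mean fitted slope.
2. **Prognosis from baseline AT(N) biomarkers.** PENet, a
   parameter-efficient multimodal network — 2 convolution + 3
   depthwise-separable convolution blocks with increasing filters for the
   3D volume, fully-connected branches for scalar biomarkers (CSF
   amyloid-beta "A", CSF p-tau "T", FDG composite, ICV), and a fused
   softmax head — is trained with SGD (batch 25, L2 5e-4 on dense weights,
   exponential learning-rate decay) under stratified cross-validation with
   within-fold volume augmentation and a fold-disjointness leakage guard.
   The convolution forward/backward passes are implemented in
   Rcpp/Armadillo; training is single-threaded and bit-reproducible.
3. **Biomarker ablation.** `run_ablation()` retrains the same
   specification on N, A(N), T(N), AT(N), N+ICV, MRI-only and
   noise-probe inputs under identical folds and seeds (paired design),
   reporting fold accuracies, pooled AUC, ROC points, DeLong tests
   (single-model vs chance and paired), plus logistic and RBF-SVM
   baselines.
4. **Statistics and subtyping.** A pipeline-honest permutation test for
   post-clustering differences, two-way repeated-measures ANOVA, Welch /
   rank-sum comparisons, tau positivity (p-tau > 21.8 pg/mL), Pearson
   chi-square, and atrophy subtypes from the hippocampal-to-cortical
   volume ratio (HpSp > 75th percentile, LP < 25th, tAD otherwise).

Because the motivating cohort data are access-restricted, the package
includes a synthetic-cohort generator (`generate_cohort()`) with two latent
decline classes, class-dependent phantom-volume atrophy, configurable
A/T/N effect sizes and an amyloid-by-tau synergy term, plus the
amyloid-positivity inclusion filter (CSF amyloid-beta < 976.6 pg/mL or
amyloid-PET SUVR > 1.11, CSF-first accounting). Every stage of the
pipeline is exercised end to end on generated cohorts.

## Worked example

```r
library(atnprog)

# a 200-subject synthetic cohort whose class depends on A, T, N and an AxT
# synergy term
coh <- generate_cohort(synergy_cohort_config(n_subjects = 200, seed = 1))

# stage 1: phenotype the trajectories
cl <- cluster_phenotypes(coh$trajectories, k = "auto")
cl$silhouette$avg_width
#>        k2        k3        k4
#> 0.5802809 0.3641593 0.3062589
table(cl$phenotype)
#>  MD  FD
#> 117  83

# stage 2: desk-scale ablation over biomarker combinations
ab <- run_ablation(coh, c("n", "tn", "atn"), desk_penet_spec(),
                   desk_train_config(seed = 1), labels = cl$phenotype)
ab
#> n        accuracy 0.530 +/- 0.099 (pooled 0.530), AUC 0.528
#> tn       accuracy 0.510 +/- 0.088 (pooled 0.510), AUC 0.504
#> atn      accuracy 0.565 +/- 0.045 (pooled 0.565), AUC 0.531
```

The average silhouette width peaks at k = 2, and the recovered MD/FD
phenotypes agree with the generator's hidden classes (ARI 0.86 here).

Single-seed runs are noisy at desk scale (a compact network, 10 epochs,
one CPU); the finding is the seed-averaged *ordering*, not the level.
Averaged over 10 seeds, AT(N) 0.597 ≥ T(N) 0.569 ≥ N 0.532: accuracy
improves as T and then A biomarkers join N — the synergy cohort's
defining property — while a pure-noise scalar probe moves N by about one
point. Downstream:

```r
st <- assign_subtypes(compute_ratio(coh$regional_volumes$hippocampal_volume,
                                    coh$regional_volumes$cortical_total_volume))
associate_subtypes(st$subtype, ab$results$atn$oof$pred)
#>        phenotype
#> subtype MD FD
#>    HpSp 37 13
#>    LP   23 27
#>    tAD  62 38
#> chi2 = 8.323, df = 2, p = 0.0156
```

The subtype proportions follow the 25/50/25 percentile rule, and the
association with the model-predicted phenotypes is tested by Pearson
chi-square (df = 2). In the synergy cohort an association is expected —
atrophy and the class labels both track the neurodegeneration latent;
generate the two independently (equal per-class atrophy factors,
`synergy_coefficient = 0`) to emulate the no-overlap situation.

`run_pipeline(pipeline_config(...))` chains all stages (simulate →
inclusion filter → cluster → statistics → ablate → subtype) with per-stage
seeds fanned out from one global seed, artifact checksums and a JSON run
report.

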
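# MorphoImprint

Does a tumor's appearance on CT reflect what it *is* (its primary-tumor
lineage) or where it *grows* (its anatomical environment)? MorphoImprint
implements a lesion-level radiomics pipeline that answers this with
unsupervised morphological clustering and a paired bootstrap concordance
test — and, because clinical cohorts of this kind cannot be shared, a seeded
synthetic 3-D lesion-phantom generator that plants a recoverable
environment "imprint" to exercise the pipeline end to end.

It is aimed at imaging scientists who want a tested, reproducible harness
for environment-vs-lineage concordance analyses: radiomic feature extraction
with class tags, embedding + clustering with an explicit model-selection
objective, bootstrap ARI inference, and an experiment grid covering
lesion-class stratification, feature-class ablation and tumor-core (mask
erosion) robustness.

## The statistic at the core

Lesions are described by radiomic features (shape, first-order intensity,
and GLCM/GLRLM/GLSZM/NGTDM/GLDM texture families, IBSI-style definitions),
standardized, embedded in 2-D with exact t-SNE, and clustered
agglomeratively. Hyperparameters (k, linkage) maximize the equal-weight
objective

    objective = 0.5 · silhouette(points, partition) + 0.5 · ARI(partition, ground truth)

The selected partition `C` is compared against two labelings of the same
lesions — tumor type `T` and anatomical environment `E` — with the adjusted
Rand index (Hubert–Arabie),

    ARI = (Index − E[Index]) / (Max − E[Index]),  Index = Σ_ij C(n_ij, 2)

under a paired bootstrap: each of B = 100 resamples draws lesion indices
with replacement once and recomputes both ARI(C, T) and ARI(C, E) on the
same draw. Reported per labeling: mean ARI, 95% percentile CI, full-data
ARI; plus the paired mean difference and the one-sided p-value
`p = (1 + #{ARI_E,b − ARI_T,b ≤ 0}) / (B + 1)` for H1: concordance with the
environment exceeds concordance with the tumor type.

## Worked example

```r
library(MorphoImprint)

cfg    <- cohortConfig(seed = 1)          # 600 lesions, 4 environments x 5 tumor types
cohort <- generateCohort(cfg)             # seeded synthetic NRRD-style volumes + metadata
se     <- extractCohortFeatures(cohort)   # 61 features x 600 lesions (SummarizedExperiment)
rep    <- runExperiment(experimentSpec(B = 100), features = se)
rep
```

```
ExperimentReport: all lesions, all features, full masks, embedding representation
  n = 600 | k = 4 | silhouette = 0.508
ConcordanceResult (paired bootstrap, B = 100 )
  mean ARI tumor_type     0.009 [0.000, 0.019] (full-data 0.003)
  mean ARI environment    0.904 [0.858, 0.937] (full-data 0.903)
  mean difference (environment - tumor_type): 0.896 [0.847, 0.927]
  one-sided p-value: 0.009901
```

Reading this: the optimizer selected four morphological clusters with
moderate cohesion (silhouette 0.51). Those clusters are almost a relabeling
of the four anatomical environments (mean ARI 0.90) and are unrelated to the
five tumor types (mean ARI 0.01); the paired difference excludes zero in
every bootstrap replicate, so the one-sided p-value sits at its B = 100
floor of 1/101 ≈ 0.0099. That is the planted structure: the generator's
environments differ in intensity mean, texture correlation length and rim
contrast, while tumor types only modulate shape weakly.

Stratified and ablated variants are one argument away:

```r
runExperiment(experimentSpec(lesion_subset = "solid_organ", B = 100), features = se)
runExperiment(experimentSpec(feature_subset = "shape", B = 100), features = se)
runGrid(experimentSpec(cohort = cfg),
        axes = list(lesion_subset = c("all", "metastatic", "solid_organ")),
        out_dir = "experiments")   # persisted artifacts + summary table
```

A thin command-line wrapper (`inst/scripts/morphoimprint`) exposes the same
operations as subcommands (`simulate`, `extract`, `erode`, `embed`,
`cluster`, `concordance`, `ablation`, `grid`, `report`) over YAML configs.

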
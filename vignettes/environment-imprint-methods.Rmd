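---
title: "Morphological concordance of CT lesions with their anatomical environment: methods and design"
author: "MorphoImprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological concordance of CT lesions with their anatomical environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

When a tumor grows in an organ, its appearance on contrast-enhanced CT is
shaped both by its lineage (the primary tumor it descends from) and by the
host tissue it grows in. MorphoImprint implements a lesion-level analysis
that quantifies which of the two dominates: lesions are described by
high-dimensional radiomic feature vectors, embedded and clustered without
supervision, and the resulting morphological clusters are compared — via the
adjusted Rand index (ARI) under a paired bootstrap — against two ground-truth
labelings of the same lesions: *tumor type* (site of the primary) and
*anatomical environment* (organ system the lesion resides in). If the
clusters track the environment and not the lineage, lesion morphology is
dominated by a host-tissue "imprint".

Because clinical cohorts of this kind cannot be redistributed, the package
ships a seeded synthetic phantom generator whose statistical structure
plants exactly this hypothesis: an environment-driven intensity/texture
imprint and a weaker lineage-driven shape effect. Everything downstream of
the generator treats its output like any NRRD cohort on disk.

## The synthetic cohort: what it emulates, and what it does not

`generateLesion()` builds one lesion as a randomly rotated, surface-perturbed
ellipsoid voxelized on a 64^3 grid at 1 mm isotropic spacing (both
configurable, including anisotropic spacing to exercise resampling). Design
of the two signal channels:

* **Environment imprint** (`environmentProfile`): the in-mask intensity is a
  Gaussian random field with environment-specific mean (HU), a fixed SD, an
  environment-specific correlation length (`texture_smoothing_sigma`,
  voxels), and an optional additive rim within one voxel of the boundary
  (e.g. rim enhancement of hepatic metastases). The smoothed white-noise
  field is standardized *exactly* (dividing by the discrete kernel's root
  sum of squares per axis), so the in-mask SD is the configured value
  regardless of sigma.
* **Lineage shape effect** (`tumorTypeProfile`): the major/short axis ratio
  distribution and a radial surface-roughness amplitude. Nothing about the
  lineage touches the intensity model, mirroring the finding the analysis is
  designed to recover: shape carries little environment signal.

Default profiles (chosen once as desk-scale stand-ins for portal-venous CT,
not measured tissue values): four environments — lung (35 HU, sigma 0.6),
hepatobiliary (95 HU, sigma 1.4, rim +20 HU), lymph node (155 HU, sigma
1.0), bone (220 HU, sigma 2.2) — with a common in-mask SD of 12 HU, so
adjacent intensity means are separated by ≥ 5 SDs (the strong-imprint
condition of ≥ 3 pooled SDs is met with margin); five tumor types with axis
ratios 1.15–1.60 and roughness 0.2–1.4 voxels; voxel noise 10 HU; background
−75 HU plus noise. The default cohort is 200 patients × 3 lesions = 600
lesions with the lesion-class mixture 8% primary / 25% lymph-node
metastasis / 67% solid-organ metastasis (the discovery-cohort proportions of
the emulated setting). Primary lesions always reside in their tumor type's
home organ; lymph-node metastases in the nodal environment; solid-organ
metastasis environments are drawn independently of tumor type (an optional
affinity matrix can change this), which makes the null behaviour of the
tumor-type ARI analyzable. At most 10 lesions per (patient, organ) are
generated, and every short axis is ≥ 10 mm: the sampling range defaults to
11–18 mm so that voxelization cannot push a lesion under the floor. The
short axis is measured as the second-largest principal-axis extent of the
mask in mm (the measurement operator is not standardized elsewhere; this is
the package's definition).

What the generator does **not** emulate: whole-CT anatomy, contrast-phase
kinetics, scanner/protocol batch effects, partial-volume effects at organ
boundaries, or inter-reader segmentation variability. Consequently a passing
planted-recovery test demonstrates that the pipeline *can* recover an
environment imprint of the planted kind and magnitude — it does not
demonstrate that real cohorts carry such an imprint, nor calibrate effect
sizes against clinical data.

### The imprint as a dial

Two properties make the generator useful as a test instrument: with all
environment profiles identical, downstream environment concordance sits at
its permutation null; widening the intensity-mean spread raises it
monotonically. The dial saturates quickly — the per-lesion mean is an average
over thousands of voxels, so once the between-environment gap exceeds a few
HU the environment groups are essentially noiseless in the mean feature —
and roughly half of each feature class is location-free (variance, skewness,
IQR, ...), which dilutes a pure mean-shift signal under full-vector
Euclidean distances on small cohorts. The test suite therefore probes the
dial in its transition region (0 / 4 / 25 HU spreads) through the intensity
feature class, on 60-lesion cohorts with the raw-feature representation;
full-scale recovery (600 lesions, all features, embedding) is exercised by
the end-to-end acceptance checks.

## Feature extraction

`extractFeatures()` runs: isotropic resampling → shape features on the mask →
gray-level discretization → first-order statistics → five texture families.
61 features in total, each tagged `shape` / `intensity` / `texture`; the
tags, not the count, are what the analysis consumes, and the panel is
deliberately a reduced, class-tagged analogue of the large filtered-image
banks used on clinical cohorts (filtered-image features are out of scope).

Numerical choices, all of which are unit-tested against independent oracles:

* **Resampling** (default target 1 mm^3): images by separable Keys cubic
  convolution (the interpolating cubic scheme), masks by nearest neighbour
  re-binarized at 0.5 — a mask should never acquire intermediate values.
  Resampling that empties a mask raises a degenerate-lesion error.
* **Discretization**: fixed bin width of 25 HU by default
  (`floor((v - min)/25) + 1`), a common CT choice; fixed bin count is
  available. A constant region discretizes to the single level 1.
* **Shape (14 features)**: voxel-count volume; *exposed-face* surface area
  (face counting rather than meshing — exactly testable, slightly larger
  than a mesh area, documented as a deliberate simplification); their ratio;
  sphericity; compactness; maximum 3-D diameter (largest center-to-center
  distance between boundary voxels; for very large boundaries a
  deterministic direction-fan prefilter bounds the candidate set); PCA axis
  lengths (4·sqrt(eigenvalue)); elongation and flatness (sqrt of eigenvalue
  ratios, defined as 1 for a single voxel); and 2-D area, perimeter and
  diameter of the largest-area axial slice.
* **First order (14 features)**: population-moment variance/skewness/
  kurtosis (kurtosis not excess), entropy in bits over the discretized
  levels, type-7 percentiles, robust MAD within the 10–90 percentile band.
* **Texture (33 features)**: GLCM (13 symmetric 3-D offsets; features per
  offset, then averaged; offsets with no valid pair are dropped), GLRLM (13
  directions, averaged), GLSZM and GLDM (26-connected zones/dependencies),
  NGTDM (26-neighbourhood means). All probability matrices normalize to 1
  within 1e−12. Degenerate single-level grids use fixed conventions (GLCM
  correlation 0, NGTDM contrast/busyness 0, coarseness capped); a mask with
  no co-occurring pair yields missing values, which the imputation step
  absorbs.
* **Erosion**: one pass of the 3-D 6-connected structuring element —
  a voxel survives iff all six face neighbours are foreground, out-of-grid
  counting as background. An empty result flags the lesion degenerate (it is
  dropped from eroded analyses with a warning, never imputed at the image
  level); a disconnected result keeps the largest 26-connected component,
  preserving connectivity.

All operators are mask-relative, so whole-voxel translation leaves the
feature vector unchanged, and shape features are invariant to intensity
rescaling; both invariances are tested.

## Embedding, clustering, optimization

Features are median-imputed and z-scored per feature (zero-variance columns
dropped with a warning). The 2-D embedding is exact t-SNE (`theta = 0`)
with deterministic PCA initialization scaled to 1e−4, perplexity 30 and
1000 iterations by default — all exposed in configuration, since embedding
hyperparameters of the emulated study are not public. Exact rather than
approximate gradients keep coordinates a pure function of input, parameters
and seed across platforms.

Clusters come from agglomerative clustering (`ward`/`complete`/`average`/
`single`; Ward restricted to Euclidean distances) cut at k clusters.
Hyperparameters (k ∈ [2, 15] × three linkages by default) maximize the
equal-weight objective `0.5·silhouette + 0.5·ARI(partition, ground truth)`.
Two open design points are resolved as configuration rather than silent
assumptions:

* **Which ground truth enters the objective** is not standardized; the
  default is the *mean* ARI against both labelings, so model selection does
  not presuppose the conclusion (environment dominance); `ari_mode` switches
  to a single labeling.
* **Search strategy**: when the evaluation budget covers the discrete
  candidate grid (the default: 42 candidates ≤ budget 50) the search is
  exhaustive — the exact maximizer of the stated objective. Under tighter
  budgets a seeded Gaussian-process surrogate with expected-improvement
  acquisition explores the grid; the trace records every evaluation either
  way, and each trace row satisfies the objective identity to 1e−12 by test.

Ties in the merge order follow `stats::hclust`'s deterministic earliest-pair
rule given the input ordering; permuting rows permutes the partition only up
to relabeling (ARI 1), which is tested.

## Concordance inference

The ARI uses the chance-corrected pair-counting form
`(Index − Expected)/(Max − Expected)` with the convention that a degenerate
comparison (`Max = Expected`, e.g. a single cluster) scores 0. The
silhouette uses Euclidean distances, scores singleton clusters 0, and scores
coincident points 0 when both mean distances vanish.

`bootstrapConcordance()` draws B = 100 lesion resamples (indices with
replacement); **one index draw serves both labelings**, making the
difference a paired comparison — the natural reading of "difference in ARI",
and strictly more powerful than independent draws. The partition is **not**
re-fitted per replicate: re-embedding and re-clustering inside every
replicate is computationally implausible at cohort scale and changes the
estimand from "stability of the observed clustering's concordance" to
"stability of the clustering procedure". Per labeling the mean and 2.5/97.5
percentile CI are reported, plus the full-data ARIs, the paired mean
difference, its CI, and the one-sided p-value
`(1 + #{diff_b ≤ 0})/(B + 1)` for H1: environment concordance exceeds
tumor-type concordance. The add-one form is the standard finite-B correction
and is bounded away from 0 at 1/(B+1) ≈ 0.0099 — consistent with reporting
"p < 0.010" at B = 100 rather than zero.

### Calibration of the one-sided bootstrap test

Simulation shows the test is well calibrated on the natural null boundary —
both labelings genuinely and equally concordant with the partition
(noisy copies at equal flip rates): rejection at nominal 5% lands inside the
binomial 99% band. At the fully degenerate point, where *both* labelings are
independent of the partition, the test is conservative (rejections stay
well below nominal): there the ARI difference is a second-order (degenerate)
statistic whose sampling SD the nonparametric bootstrap overestimates.
This is a property of the procedure itself, not of this implementation
(pairing already reduces it; independent draws would be worse). Practically:
p-values are trustworthy, erring on the safe side, in the regime the
analysis targets — where at least one labeling genuinely tracks the
clusters. The unit suite asserts exactly these two behaviours.

Contingency tables are row-normalized (each ground-truth class distributed
across clusters, rows summing to 100%), matching the layout of the result
tables this analysis conventionally reports.

## The experiment grid

`runExperiment()` executes one fully specified cell: lesion subset (all /
metastatic, dropping primaries / solid-organ, additionally dropping nodal
metastases), feature-class subset, mask variant (full or eroded),
representation (embedding or raw standardized features), with independent
named seeds for embedding, optimizer and bootstrap. Each cell re-runs
standardization, embedding and optimization *on its own subset* — per-subset
cluster counts and silhouettes only make sense that way — and
`runGrid()` shares feature extraction across cells with the same mask
variant. An optional environment-grouping map (site → organ system) is
applied to the metadata before analysis; the default is identity, since any
grouping is cohort-specific. Every artifact (features, embedding, partition,
concordance JSON with full bootstrap vectors, contingency tables, trace,
report) is persisted deterministically: re-running a spec with identical
seeds reproduces byte-identical files, which is both tested and the reason
provenance stamps carry a config hash and seeds but no timestamps.

## Problem sizes used by the tests

Oracle-based checks run at their natural sizes (500 ARI pairs at n ≤ 12, 100
silhouette sets at n ≤ 50, 200 erosion blobs, 100 naive-agglomeration
instances at n ≤ 8, 200 planted-null bootstrap datasets at n = 200). The
planted-structure acceptance run uses the full default condition: ten
600-lesion cohort seeds end-to-end, plus the feature-class ablation and the
eroded-mask run on the first cohort. Module-level properties that would
repeat the full pipeline tens of times (the imprint dial, the null control)
run on 60-lesion cohorts with the raw representation — the package's choice
of a size at which the property is still decisive.

## Known limitations

* The lesion appearance model is a stand-in: no generative model of real
  lesion morphology was available to emulate, so all distributional choices
  (ellipsoids, Gaussian fields, rim offsets) are synthetic conventions.
* The feature panel is a reduced analogue (61 features; no filtered-image
  bank), so per-feature parity with large clinical radiomics extractions is
  neither claimed nor tested.
* Surface area by face counting systematically exceeds mesh-based area for
  smooth shapes; sphericity/compactness inherit this convention.
  Within-package comparisons are unaffected.
* The bootstrap difference test is conservative when *neither* labeling
  relates to the clusters (see calibration above).
* Multiple-testing correction across grid cells is intentionally absent,
  matching the emulated analysis; interpret per-cell p-values accordingly.
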
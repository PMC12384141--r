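---
title: "Methods: peritumoral radiomics, probability stacking, and explainable response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peritumoral radiomics, probability stacking, and explainable response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

radstack predicts response to immune checkpoint inhibition in advanced
non-small cell lung cancer (NSCLC) from CT texture around and inside the
tumor together with routine clinical covariates, and explains each
prediction in plain language. This vignette documents the models, the
tunable parameters, the numerical conventions, and what the synthetic-data
tests do and do not establish.

## The modelling problem

Each patient contributes one or more segmented lesions on a chest CT
(strongly anisotropic: sub-millimetre pixels in-plane, roughly 5 mm slice
spacing) plus PD-L1 score, tumor mutational burden (TMB), smoking status and
age, a binarized treatment response, and censored progression-free survival
(PFS). Modelling is instance-wise (one row per lesion, patient-level
covariates repeated) with patient-level fold assignment so that lesions of
one patient never straddle a training/test boundary.

## Radiomics engine

For each lesion the volume is cropped to the mask bounding box padded by 30
pixels in x/y and 10 in z; the peritumoral shell is built by dilating the
tumor mask with a 3x3 square element, 5 iterations, independently per axial
slice (no growth across ~5 mm slices; at the 0.83 mm median pixel this is a
4.15 mm margin); intensities are min-max normalized to [0, 1] and quantized
into 32 fixed bins.

Per voxel, a 3x3x3 window (truncated at the border rather than padded) is
scanned with the 13 canonical symmetric distance-1 offsets. Each offset
yields a symmetric, normalized gray-level co-occurrence matrix from which
eight Haralick statistics are computed; the 13 per-offset values are
averaged into one map per statistic. Conventions that had to be fixed:

* Entropy uses log base 2; a constant window has Energy 1 and Entropy 0.
* `Correlation` is the normalized covariance
  $\sum_{ij}(i-\mu)(j-\mu)p_{ij}/\sigma^2$, defined as 0 when
  $\sigma^2 = 0$; `HaralickCorrelation` is the 1-based autocorrelation
  $\sum_{ij}(i+1)(j+1)p_{ij}$. For a symmetric GLCM any mean-shifted
  "Haralick correlation" collapses algebraically onto the covariance form,
  so the autocorrelation reading is the one that keeps the two maps
  distinct.
* Offsets that admit no voxel pair inside a truncated window are excluded
  from the 13-offset average.

A spacing-aware gradient-magnitude map (central differences, one-sided at
borders, 2D fallback for single-slice axes) is the ninth map. Each map is
summarised over each region by mean, median, population variance, skewness,
Fisher (excess) kurtosis and the type-7 10th/90th percentiles: 9 maps x 7
statistics = 63 named features per region. Regions with fewer than two
voxels are an explicit error (variance undefined).

Quantization depth (32 levels) and the per-voxel window radius are exposed
in `radiomics_config()`; 32 fixed bins over [0, 1] is standard radiomics
practice and keeps tiny-window GLCMs non-degenerate.

## Two-stage feature selection

Stage one ranks features by mean decrease in impurity: a 500-tree random
forest per stratified CV fold (5 by default), per-forest importances
normalized to sum to one, averaged across folds. Stage two adds features in
rank order, evaluates each prefix by out-of-fold AUC, and keeps the prefix
with the best mean AUC, smallest size on ties (parsimony). Forest
hyperparameters (500 trees, sqrt-features per split, unrestricted depth) are
recorded in the config; all fits are seeded and single-threaded for exact
reproducibility.

## Response-model matrix and probability stacking

Region forests on the selected tumoral (fT) and peritumoral (fpT) features
produce response probabilities pT, ppT and (on the union) pT_all. On the
training cohort these are strictly out-of-fold (3-fold stratified CV); test
probabilities come from a refit on the full training cohort. The stacked
model combines (PD-L1 score, TMB, ordinal smoking never=0/former=1/
current=2, age, pT, ppT) in one forest; variants use pT_all or the raw
selected features. Subject-wise probabilities average a patient's lesion
probabilities (a max rule is available). Metrics are AUC (rank statistic,
ties half-credit), accuracy and recall at threshold 0.5.

Internal CV fold counts are capped at the minority-class size so very small
cohorts still cross-validate; the patient-level split plan itself never
relaxes.

## Bayesian network layer

Clinical variables are discretized (PD-L1 0 / 1-49 / >=50 percent; TMB at
10 mut/Mb; age in decade bins; pT/ppT at 0.7, boundary to "high").
Structure is learned by hill climbing over add/delete/reverse single-edge
moves under the BDeu score with equivalent sample size 1.0 (exposed);
candidate moves are enumerated in a fixed lexicographic order, so the
search is deterministic. In the out-of-structure mode the discretized pT
and ppT are attached afterwards as children of outcome; the in-structure
mode includes them in the search. No orientation constraint is imposed
toward the outcome — the learned graph is allowed to orient edges
"wrongly", as population-level score-based search sometimes does; an edge
blacklist supports sensitivity analysis. The classifier uses posterior-mean
(Dirichlet-smoothed) CPTs and exact inference by enumeration, which is
cheap on these few-node networks.

## Survival contrast

Predicted responders (thresholded subject probability) are contrasted by
Kaplan-Meier curves, the two-group log-rank test, and restricted mean
survival time computed as the exact area under the KM step function up to
32 months. When the horizon exceeds follow-up the curve is extended flat
(with a warning); events are processed before censorings tied at the same
time.

## Explanation layer

The learned graph's neighbours of outcome, a hypothesis table of
literature-grounded directions (high PD-L1 -> response, high TMB ->
response, high pT/ppT -> non-response, current/former smoker -> response,
age > 65 -> non-response), and the patient's categorical levels are turned
into subject-predicate-object sentences; sentences contradicting the
hypothesis table for the patient's outcome are discarded. Retrieval uses a
deterministic hashed bag-of-tokens embedder (256 buckets, L2-normalized) in
place of a hosted sentence-transformer; the embedder is a pluggable
function, so an external model can be injected without touching the
pipeline. Responses are ranked by cosine similarity; a response is retained
only when it beats the best competitor for the same feature by at least
tau, which makes retention monotone (tau = 0.05 retains a subset of
tau = 0.01). The answer relevancy metric is the mean cosine between
generated-response embeddings and the question embedding, in [0, 1] for
this non-negative embedder. Report generation is a deterministic template
by default, with the same pluggable-client contract.

The tau rule deserves a note: "difference of answer relevancy" admits
several readings; the per-feature margin was chosen because it is the
simplest rule under which a stricter threshold provably yields fewer,
more clearly relevant responses.

## Synthetic cohort: what it emulates and what it does not

The generator produces, per lesion, a 32 x 32 x 10 subvolume with spacing
drawn from 0.59-0.98 mm in-plane and 4.8-5.0 mm in z; an irregular blob
mask (perturbed ellipsoid, 6-14 voxels in-plane diameter by default — small
enough to keep desk-scale runs fast, configurable upward); and a
class-dependent texture: zero-mean in-plane correlated noise whose
correlation length grows with the effect size for responders, standardized
so mean intensity and marginal variance are untouched — only local texture
(GLCM entropy, inverse difference moment, local variance) separates the
classes. Two details matter for honest region attribution:

* a one-voxel guard ring at the tumor boundary is left unplanted, so
  radius-1 texture windows on one side of the boundary cannot absorb the
  other region's signal;
* every volume carries fixed air (0) and dense-tissue (1) anchor voxels,
  as real CT fields of view do, so min-max normalization rescales all
  volumes identically and cannot leak class information across regions.

Clinical variables are sampled ancestrally from a configurable causal DAG;
the default has outcome as a root at the configured responder fraction
(51/187 by default) with PD-L1 and TMB bins as its children and
cohort-like marginals elsewhere. The real cohort's TMB is nearly degenerate
(99% above 10 mut/Mb); the generator keeps a usable minority fraction so
the variable can participate in structure learning. PFS is exponential
(default medians 16 months for responders, 5 for non-responders — typical
of ICI cohorts) with independent exponential censoring calibrated to hit
the target censoring probability exactly, which keeps a closed-form RMST
available as an oracle.

The phantom is not an anatomical lung: no airways, vessels, lobes or
realistic HU distributions, no segmentation error, no scanner effects.
Passing recovery tests therefore shows that the pipeline finds the signal
it was told to find and nothing else (no leakage); it does not show that
any particular AUC is attainable on clinical data.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; stage seeds derive
from one master seed, forests are single-threaded, and identical configs
reproduce byte-identical outputs. The test suite runs the planted-signal
recovery at 60-patient cohorts over 20 seeds, structure recovery at
n = 5000 over 20 seeds, survival convergence at n = 2000, and the
no-signal null at 30-patient cohorts over 6 seeds with pooled held-out
predictions — sizes chosen so the whole suite stays desk-scale while the
binomial/multinomial error bands remain tight enough to be meaningful.

## Known limitations

* Per-voxel GLCM maps at radius 1 mix information across the tumor
  boundary by construction; the guard ring in the generator compensates in
  simulation, but on real data tumoral and peritumoral features are not
  perfectly decoupled at a 1-voxel scale.
* The incremental selector inspects prefixes of one MDI ranking; feature
  interactions that only help in non-prefix subsets are invisible to it.
* Exact BN inference enumerates the joint; it is intended for the
  few-variable clinical networks here, not for large graphs.
* The "train-val" rows of the model matrix are computed after feature
  selection on the same training cohort and are optimistic by design, as
  in the study design they mirror; held-out rows are the honest ones.
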
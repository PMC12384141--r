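# radstack

Predicting immunotherapy response in non-small cell lung cancer (NSCLC)
from CT texture and clinical covariates — and explaining each prediction —
with every stage testable offline on synthetic cohorts with planted,
recoverable signal.

Checkpoint-inhibitor response is hard to anticipate from any single
biomarker. Radiomic texture of the tumor and, notably, of the *peritumoral*
margin (the few millimetres of tissue around the tumor, where the immune
infiltrate lives) carries complementary information to PD-L1 score, tumor
mutational burden (TMB), smoking status and age. radstack implements the
full analysis chain for this setting, for imaging/ML researchers who want a
reproducible, leakage-audited reference pipeline:

1. **Synthetic cohort generator** — anisotropic CT subvolumes (sub-mm
   in-plane, ~5 mm slices) with irregular blob tumor masks, class-dependent
   texture planted in a chosen region, clinical tables sampled from a
   configurable causal DAG, and censored exponential progression-free
   survival. Real-data mode accepts NIfTI volumes + masks and a CSV table.
2. **Radiomics engine** — per-voxel 3D gray-level co-occurrence (GLCM)
   Haralick maps (13 symmetric distance-1 offsets averaged per voxel) plus
   a spacing-aware gradient map; 9 maps x 7 statistics = **63 features per
   region**, for the tumor and for a 5-pixel axial peritumoral margin
   (4.15 mm at the 0.83 mm median pixel).
3. **Two-stage feature selection** — random-forest mean decrease in
   impurity (MDI) ranking under cross-validation, then an incremental
   out-of-fold AUC scan over ranking prefixes.
4. **Probability stacking** — region forests produce out-of-fold response
   probabilities pT (tumoral), ppT (peritumoral), pT_all (combined); the
   stacked forest combines them with the clinical variables. AUC, accuracy
   and recall are reported for the full matrix of model variants, instance-
   and subject-wise.
5. **Bayesian network layer** — hill-climbing structure search under the
   BDeu score over discretized clinical variables and outcome, with pT/ppT
   attached as outcome children (or included in the search), and an
   exact-inference discrete classifier.
6. **Survival contrast** — Kaplan-Meier curves, log-rank test, and
   restricted mean survival time (RMST, exact step-function area to 32
   months) between predicted response groups.
7. **Explanation layer** — hypothesis-grounded triplet sentences from the
   learned graph, ranked by cosine similarity under a deterministic offline
   embedder, filtered by a relevancy margin τ, rendered as patient reports;
   report quality is scored by the answer relevancy metric
   ARM = (1/N) Σᵢ cos(Eg⁽ⁱ⁾, Eo).

## Worked example

```r
library(radstack)

cfg <- run_config(cohort = cohort_config(n_patients = 60, seed = 7),
                  scan_range = c(1, 15), seed = 7)
run <- run_pipeline(cfg)
run$models$metrics
#> # A tibble: 11 × 6
#>    method              level      auc accuracy recall     n
#>    <chr>               <chr>    <dbl>    <dbl>  <dbl> <int>
#>  1 RF-train-val-fT     instance 0.765    0.788  0.385    52
#>  2 RF-train-val-fpT    instance 1        1      1        52
#>  3 RF-train-val-fT-fpT instance 1        0.981  0.923    52
#>  4 RF-fT               instance 0.523    0.708  0.125    24
#>  5 RF-fpT              instance 1        1      1        24
#>  6 RF-fT-fpT           instance 1        1      1        24
#>  7 RF-Clin             instance 0.625    0.625  0        24
#>  8 RF-Clin-pT_all      instance 1        1      1        24
#>  9 RF-Clin-pT-ppT      instance 1        1      1        24
#> 10 RF-Clin-fT-fpT      instance 1        1      1        24
#> 11 RF-Clin-pT-ppT-Sub  subject  1        1      1        16
```

The generator's default plants texture signal **only in the peritumoral
shell**, and the metrics show exactly that: the held-out tumoral-feature
model (`RF-fT`, AUC 0.52) is at chance while the peritumoral model
(`RF-fpT`, AUC 1.00) recovers the signal, and stacking keeps it. The
predicted groups separate in survival:

```r
run$survival
#> <survival_contrast> log-rank chi-sq 11.05 (p = 0.000887); RMST gain 19.40 months at 32 months
```

(the generator's responders have median PFS 16 months against 5, so a
large positive RMST gain is the planted truth), and each test lesion gets
a hypothesis-grounded report:

```r
run$reports[[5]]
#> Predicted outcome: responder. Supporting evidence: tumoral probability low
#> is associated with positive response; TMB high is associated with positive
#> response.
```

Individual stages are plain functions on data frames and pipe together:
`generate_cohort()`, `extract_cohort_features()`, `rank_by_mdi()`,
`incremental_auc_selection()`, `stratified_kfold_split()`,
`run_response_matrix()`, `hill_climb_search()`, `fit_bayes_classifier()`,
`km_estimate()`, `rmst_difference()`, `categorize_patient()`,
`rank_features()`, `generate_report()`. Result objects have `tidy()` /
`glance()` / `autoplot()` methods. See `vignette("methods")` for the models,
conventions and limitations.

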
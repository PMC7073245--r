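# histoprog

Prognostic analysis of H&E histopathology images, end to end and fully
testable at desk scale.

Digital pathology cohorts such as TCGA-LIHC (hepatocellular carcinoma)
pair whole-slide H&E images with clinical survival and molecular pathway
data. `histoprog` implements the complete analysis chain that connects
them:

1. **Stain handling.** Per-channel optical density
   `OD_c = -log10(I_c / I_0)` makes the two stain contributions additive
   (Beer–Lambert). The image-specific 3×2 stain matrix is estimated with
   the Macenko procedure (SVD plane + extreme-angle percentiles), images
   are normalized to a reference stain appearance by rescaling per-stain
   concentration maxima, and color augmentation multiplies the two
   concentration channels by independent Uniform(0.95, 1.05) draws.
2. **Patches and features.** Random square crops (256² or 512², 20 per
   augmented image, with a configurable tissue filter) are summarized by
   pluggable, deterministic feature extractors; per-crop vectors are
   median-aggregated to one vector per image and per subject. The named
   backends reproduce the feature dimensions forced by the classic CNN
   architectures (VGG-16 late-stage channels 128+256+512+512 = 1408;
   Inception-V3/ResNet-50 pooled final block = 2048).
3. **Visualization and classification.** PCA to 10 components followed by
   t-SNE (perplexity 15) for 2-D maps; stratified 6-fold cross-validated
   linear SVM (C = 1) with per-fold ROC AUC and pooled average precision
   for tumor/normal separation.
4. **Survival.** Univariate Cox proportional hazards per feature (Efron
   ties, score/log-rank test, selection at p ≤ 0.05); elastic-net Cox
   (α = 0.5, 10-fold cross-validated λ at minimum partial-likelihood
   deviance) with Harrell's C on out-of-fold risk and a median-split
   log-rank test; Kaplan–Meier estimation throughout.
5. **Subgroups.** K-means (K = 2–12, k-means++ style multi-start) on the
   features significant for both OS and DFS, with mean silhouette and
   Davies–Bouldin model selection, subgroup survival comparison, and
   cross-model overlap tables.
6. **Pathways.** Firehose-PARADIGM IPL matrices (`19_EPHB3`-style entity
   ids) are correlated with image features (Pearson, Benjamini–Hochberg
   at 0.05) and tested for differential activity between subgroups with
   an empirical-Bayes moderated t (BH at 0.1).

A first-class synthetic-data module generates every input with known
ground truth — Beer–Lambert H&E images with a known stain matrix, cohorts
with planted class/cluster/survival structure (exponential Cox model,
calibrated uniform censoring), and IPL matrices with calibrated feature
coupling — so each stage is validated against the truth that generated
its input.

## Worked example

Stain ground truth is recovered from a simulated H&E image:

```r
library(histoprog)

sim <- simulate_he_image(width = 400, height = 300, seed = 1)
est <- estimate_stain_matrix(sim$image)
est
#> <stain_model>
#>   hematoxylin  eosin
#> R      0.6486 0.0701
#> G      0.7038 0.9914
#> B      0.2898 0.1102
#> max_density: 1.124 1.001

norm  <- normalize_to_reference(sim$image)
aug   <- augment_image(norm, augmentation_policy(count = 50, seed = 2))
crops <- sample_crops(aug[[1]], size = 256, count = 20, seed = 3)
length(extract_crop_features(crops[[1]], feature_extractor("vgg16")))
#> [1] 1408
```

The recovered hematoxylin and eosin columns are within 0.3° of the
generating vectors. On a simulated cohort the analysis chain reads:

```r
cohort <- simulate_cohort(
  n_tumor = 150, n_normal = 50, n_features = 50,
  class_shift = 1.5, n_clusters = 2, cluster_shift = 3,
  survival_beta = c(rep(0.8, 5), rep(0, 45)), censor_fraction = 0.25,
  seed = 7
)

classify_cv(cohort$features, seed = 1)
#> <classification_report> 6-fold CV, mean AUC 0.993, AP 0.996

os  <- screen_features(cohort$features, cohort$survival, endpoint = "OS")
dfs <- screen_features(cohort$features, cohort$survival, endpoint = "DFS")

fit_elasticnet_cox(cohort$features, cohort$survival, endpoint = "OS", seed = 2)
#> <encox_fit> OS: 18/50 nonzero features, lambda 0.1155, C-index 0.842,
#>   log-rank p 3.99e-28

tumor <- cohort$features[cohort$features$label == "tumor", ]
scan  <- cluster_scan(
  feature_matrix(tumor)[, intersect_significant(list(os, dfs))], seed = 3
)
scan
#> <cluster_scan> K in 2..12, chosen K = 2 (silhouette 0.532)

subgroup_survival(scan$labels, cohort$survival, endpoint = "OS")
#> <subgroup_survival> OS: 2 groups, C-index 0.672, log-rank p 1.16e-11
```

The classifier separates the planted classes almost perfectly (mean AUC
0.993); the elastic-net model concentrates on the five features that
truly drive the hazard and ranks subjects well out of fold (C = 0.842,
chance is 0.5); the scan recovers the planted K = 2, and the two
subgroups differ strongly in overall survival. `tidy()`, `glance()` and
`autoplot()` methods are available on all fitted objects, and
`run_pipeline(pipeline_config(...))` executes the whole chain from one
seeded configuration.

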
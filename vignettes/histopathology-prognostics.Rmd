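---
title: "Methods: from H&E stains to survival subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from H&E stains to survival subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoprog)
```

`histoprog` chains six analysis stages: stain handling, patch sampling,
feature extraction and aggregation, tumor/normal classification, survival
modelling, and subgroup/pathway analysis. This vignette explains the model
behind each stage, the parameters that matter, the numerical choices, and
what the synthetic-data generators do and do not establish.

## Stain model and deconvolution

Light transmitted through a two-dye H&E section follows the Beer–Lambert
law: with background intensity $I_0$ (default 255), the per-channel
optical density $OD_c = -\log_{10}(\max(I_c, 1)/I_0)$ is a non-negative
linear mixture of the two stains,

$$ OD = M\,c, \qquad M \in \mathbb{R}^{3\times 2},\; c \ge 0, $$

where the columns of $M$ are unit-norm absorption spectra for hematoxylin
and eosin and $c$ holds the per-pixel stain concentrations. Log base 10 is
the convention of the classical deconvolution literature; any other base
only rescales concentrations.

`estimate_stain_matrix()` implements the Macenko construction: tissue
pixels (OD Euclidean norm above `od_min = 0.15`) are projected onto the
plane of their top two singular directions, and the directions at the 1st
and 99th percentile of the polar angle (`angle_percentile = 1`) are taken
as the stain vectors. The assumptions are that (i) exactly two dyes are
present, and (ii) some pixels are nearly pure in each dye. Violations are
surfaced as errors: fewer than 100 tissue pixels raises an
insufficient-tissue error, and a top-two singular value ratio above 50
(no second stain direction) raises a degenerate-stain error. Column
identity is fixed deterministically by assigning hematoxylin to the
column with the larger red-channel OD, since hematoxylin absorbs strongly
in red and eosin does not.

Concentrations are recovered per pixel by non-negative least squares onto
the two columns. Because there are only two variables, the solution is
closed form: if the unconstrained $2\times 2$ solve is feasible it is
optimal; otherwise the best single-stain fit is the larger clamped
projection (for unit columns the residual is
$\lVert y\rVert^2 - \max(0, y^\top m)^2$). The unit tests check this
against an independent active-set NNLS solver.

**Normalization** rescales each stain's concentrations by
`reference$max_density / source$max_density` and re-renders through the
reference matrix. `max_density` is the 99th percentile of tissue-pixel
concentrations — robust to the handful of saturated pixels that a maximum
would latch onto. The default reference uses the classical published H&E
OD vectors, H = (0.65, 0.70, 0.29) and E = (0.07, 0.99, 0.11),
normalized; no cohort-specific target is assumed.

**Augmentation** perturbs color in density space: each of the (default
50) augmentations multiplies the two concentration channels by
independent Uniform(0.95, 1.05) draws and re-renders through the source
matrix. The multiplier range is a genuinely open choice — a mild ±5%
perturbation changes stain intensity without altering morphology, so the
class structure downstream is preserved. The bounds are exposed on
`augmentation_policy()` for users who want harsher augmentation.

## Patches, features and aggregation

Crops are sampled uniformly with replacement over all valid origins
(0-based, half-open), so crops may overlap. A tissue filter rejects crops
whose fraction of pixels with mean OD > 0.15 falls below
`min_tissue_fraction = 0.5`, redrawing up to 100 times and keeping the
best-seen crop (with a warning) if the image cannot satisfy the filter;
setting the threshold to 0 disables filtering entirely. Blank crops carry
no signal and would dilute the aggregated features, which is why the
filter defaults on even though background rejection is often left
unstated in applied work.

Per-crop feature extraction is pluggable. The shipped backends are
deterministic and weights-free: per-channel intensity histograms (32 bins
per channel, plus per-channel mean and sd) pass through a fixed random
projection seeded by the backend name. The named backends differ only in
output dimension, which follows the channel arithmetic of the
corresponding architecture — spatial maps reduced to one scalar per
channel force 128 + 256 + 512 + 512 = 1408 features for the four late
VGG-16 stages and 2048 for the pooled final block of Inception-V3 or
ResNet-50. Global average pooling is the reduction that makes those
counts come out, which is why it is the assumed pooling. Pretrained-weight
extraction is deliberately out of scope (no deep-learning runtime is a
dependency); any external extractor plugs in through `extract_fun` with
its own output dimension.

Aggregation is the elementwise **median** across all crops of all
augmentations of an image, and again across the images of a subject. The
median is permutation-invariant, monotone in every coordinate, and robust
to the occasional degenerate crop. The per-crop matrix is retained as an
intermediate for inspection.

## Embedding and classification

`embed_features()` reduces to 10 principal components (exact SVD,
centered) and then runs t-SNE to two dimensions at perplexity 15. The
t-SNE implementation is exact ($O(n^2)$ affinities, per-point bisection
to match the perplexity entropy, early exaggeration ×12 for 100
iterations, momentum 0.5→0.8 over 500 iterations). At cohort scale —
hundreds of subjects — the quadratic cost is negligible, so no tree
approximation is needed; the embedding is seeded and bit-reproducible.

`classify_cv()` runs a stratified 6-fold cross-validated linear SVM with
cost C = 1. Features are standardized with **train-fold** statistics
before fitting — raw extractor activations have heterogeneous scales, and
fold-internal standardization avoids information leaking from held-out
samples. AUC is computed per held-out fold and averaged; average
precision is computed once from the pooled out-of-fold decision scores,
the simplest construction consistent with reporting a single
precision-recall curve per model. The positive class is the
alphabetically larger label, which makes "tumor" positive against
"normal" without extra configuration.

## Survival modelling

Univariate screening fits one Cox proportional hazards model per feature
(Efron tie handling, the standard default of the survival ecosystem) and
selects features with score (log-rank) test p ≤ 0.05. Near-constant
features (variance < 1e−12) are excluded with a warning rather than
fitted; subjects missing an endpoint are dropped for that endpoint only.

The multivariate model is an elastic-net-penalized Cox fit with mixing
α = 0.5 (equal lasso and ridge) over a 100-value log-spaced λ path; λ is
chosen to minimize mean 10-fold cross-validated partial-likelihood
deviance. The minimum-deviance rule (not one-standard-error) is the
common default and the natural reading when nothing else is specified.
Three evaluation constructions are fixed explicitly so results are
reproducible:

* the concordance index is Harrell's C (risk ties count ½) computed on
  **prevalidated** out-of-fold linear predictors, not on refitted
  in-sample risk;
* the fold-wise C mean ± sd is also reported, since a single pooled C and
  a fold-averaged C answer slightly different questions;
* the reported log-rank p splits subjects at the **median out-of-fold
  risk score** — a continuous-risk model has no canonical two-group test,
  so the construction is named rather than left implicit.

## Subgroup discovery

K-means (multi-start, `n_init = 10`, seeded) scans K = 2–12 on the
standardized features significant for both OS and DFS. Partition quality
is scored by mean silhouette (higher better) and the Davies–Bouldin index
(lower better); the chosen K maximizes silhouette with Davies–Bouldin as
the tie-break. When the two metrics disagree a deterministic rule is
required, and silhouette wins because it is the metric defined directly
on inter-point distances rather than on cluster centroids. Subgroups are
relabeled so that the highest-numbered group has the largest Kaplan–Meier
area — "group 2 is the better-prognosis group" then holds by
construction, making labels comparable across extractors.

## Pathway correlation and differential activity

IPL matrices are parsed in the Firehose PARADIGM dialect
(`"<pathwayIndex>_<concept>"` ids; malformed ids fail loudly with the
offending row). Pearson correlations between every selected feature and
every entity are tested on the exact sample-id intersection (minimum 3
shared samples), with Benjamini–Hochberg adjustment pooled **globally
across all feature × entity pairs** — the conservative literal reading
when the pooling scope is unstated.

Differential activity between two subgroups uses an empirical-Bayes
moderated t: entity variances inform a scaled inverse-chi-squared prior
fitted by moments on log variances (with a Newton inversion of the
trigamma function), each entity's variance is shrunk toward the prior,
and the statistic gains the prior degrees of freedom. The implementation
reproduces the reference empirical-Bayes package to machine precision in
the test suite, and a plain Welch t is available as a fallback
(`method = "welch"`). Significance is BH ≤ 0.1.

## Synthetic data: what it does and does not establish

The generators produce every input the pipeline consumes, with known
truth:

* `simulate_he_image()` renders nucleus disks (high hematoxylin) in an
  eosin cytoplasm with Gaussian concentration noise through a known stain
  matrix — so stain estimation can be scored in degrees against truth.
* `simulate_cohort()` draws Gaussian features with a planted class shift,
  planted mean-shift clusters among tumor samples, and survival from an
  exponential Cox model (hazard $\lambda_0 e^{x^\top\beta}$, default
  baseline 1/1000 per day) with independent uniform censoring whose
  horizon is solved numerically (`uniroot`) to hit the target censoring
  fraction in expectation — censoring stays non-informative.
* `simulate_ipl()` builds coupled entities as
  $r\,z(x) + \sqrt{1-r^2}\,\varepsilon$, achieving the target correlation
  in expectation.

These fixtures validate *correctness and calibration*: stain recovery
below 3° on average, type-I selection near 5% on null features,
elastic-net support recovery, planted-K recovery, FDR control. They do
**not** establish performance on real slides: synthetic images lack
tissue texture, scanner artifacts, pen marks and stain variability beyond
the two-dye model, and Gaussian cohorts lack the heavy tails and
correlation structure of real CNN activations. Passing tests mean the
machinery is right, not that real-data AUCs or C-indices will match.

## Problem sizes and runtime choices

The test and acceptance suites run on deliberately modest sizes — images
of a few hundred pixels, cohorts of 100–500 subjects, 10–500 features,
200 null-correlation replicates — chosen so the full suite completes in
well under a minute while keeping Monte-Carlo standard errors small
relative to the asserted tolerances. The acceptance script averages the
null concordance index over 20 independent risk draws on one 500-subject
cohort: the estimand is the expectation of C for risk scores independent
of survival, and averaging draws is plain variance reduction.

## Known limitations

* No pyramid-slide (`.svs`) reader; inputs are PNG/TIFF rasters already
  extracted at a workable level. Block-mean downsampling with ceiling
  rounding stands in for pyramid-level reduction.
* The stain model is strictly two-dye; necrosis, ink and other
  chromophores violate it and will distort estimated vectors.
* No pretrained CNN weights ship with the package; the named backends
  reproduce dimensions and determinism, not learned representations.
* No time-dependent covariates, competing risks, or proportionality
  diagnostics in the survival stage; no consensus or hierarchical
  clustering alternatives.
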
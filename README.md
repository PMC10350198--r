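# lesionsubtype

Predicting severe post-stroke aphasia from whole-brain morphometry and
lesion anatomy, and discovering atrophy subtypes from what the classifier
attends to.

## The problem

Aphasia severity after a left-hemisphere stroke is usually summarized by
the Western Aphasia Battery aphasia quotient (WAB-AQ, 0-100; severe
aphasia: WAB-AQ ≤ 50, about 35% of chronic cohorts). Lesion size and
location explain much of the variance, but tissue integrity *beyond* the
lesion — the three-dimensional distribution of atrophy — carries additional
prognostic information. This package implements, as a tested R pipeline,
an analysis that asks three questions:

1. Can a 3D convolutional network (CNN) on single-channel *ordinal
   morphometry maps* — CSF/GM/WM segmentations merged with the lesion
   (codes 0-4, lesion superseding tissue, downsampled to 8 mm, cropped,
   scaled to [-1, 1]) — predict severe aphasia better than tuned SVM
   baselines (linear/RBF, optional PCA/ICA reduction), under one
   preallocated repeated nested stratified cross-validation plan
   (20 × 6 outer × 8 inner, stratified by the granular WAB-R categories)?
2. Where does each model look? Grad-CAM++ and baseline-referenced
   path-gradient attribution for the CNN, kernel SHAP for the SVM, compared
   across lesion / perilesional / extralesional ROIs and their right-
   hemisphere homologues.
3. Do individuals fall into distinct atrophy subtypes? Consensus clustering
   of saliency maps (eta-squared distance k-means over 60% voxel
   subsamples, Hartigan dip screening, PAC model-order selection, affinity-
   propagation exemplars), and chi-square meta-analytic decoding of the
   exemplar maps against a topic-tagged study corpus.

Because the real cohort sits behind a controlled-access archive, the
package ships a synthetic cohort generator (`generate_cohort()`) with
planted ground truth — left-hemisphere lesions of variable size, K
multi-focal atrophy patterns whose burden drives severity independently of
lesion size, and WAB-AQ-like scores calibrated to 35% severe prevalence —
so the full pipeline runs and is tested end to end with no downloads.

## Core quantities

* Ordinal map: voxel code c ∈ {0 background, 1 CSF, 2 GM, 3 WM, 4 lesion},
  scaled to 2c/4 − 1; modal (majority) pooling with ties to the highest
  code.
* Class-weighted loss: w_c = 1/freq_c; cosine warm restarts:
  rate = floor + ½(base − floor)(1 + cos(π t/T_i)), T_i = 50·2^i.
* Metrics from the pooled confusion table: recall = severe-class accuracy,
  balanced accuracy = mean of class accuracies, F1 = harmonic mean of
  precision and recall. An always-severe predictor at 35% prevalence scores
  F1 = 2·0.35/1.35 ≈ 0.52; an always-majority predictor scores 0.
* Map similarity: η² = 1 − SS_within/SS_total computed pointwise (1 for
  identical maps, sensitive to offsets); clustering distance 1 − η².
* PAC: fraction of consensus entries strictly inside (0.1, 0.9).

## Worked example

```r
library(lesionsubtype)

co   <- generate_cohort(cohort_spec(n_subjects = 60, grid_shape = c(24, 28, 24),
                                    noise_sd = 1, seed = 7))
prep <- preprocess_cohort(co, factor = 4)       # 2 mm -> 8 mm ordinal maps
y    <- as.integer(granular_category(co$truth$wab_aq)$severe)

mean(y)                                          # realized severe prevalence
#> [1] 0.3333333

sp  <- split_train_validation(1:60, 0.3, granular_category(co$truth$wab_aq)$category)
cfg <- cnn_config(channels = c(8, 16), convs_per_block = c(1, 1),
                  dropout_rate = 0.6, base_learning_rate = 1e-2,
                  input_shape = prep$dims, allow_small = TRUE)
fit <- train_cnn(build_cnn(cfg), prep$features[sp$train, ], y[sp$train],
                 prep$features[sp$validation, ], y[sp$validation],
                 training_schedule(total_epochs = 120, batch_size = 32))
pred <- predict_and_latent(fit, prep$features[sp$validation, ])
confusion_metrics(y[sp$validation], pred$labels)[, c("f1", "balanced_accuracy")]
#>          f1 balanced_accuracy
#> 1 0.8571429         0.9166667
```

The F1 of 0.86 on held-out subjects sits far above the 0.52 always-severe
baseline: the network has learned the lesion- and atrophy-driven severity
structure planted by the generator. `grad_cam_pp(fit, prep$features[i, ])`
then yields the voxelwise attention map for subject i, and the
`analysis/` scripts (`01_simulate.R` … `09_permutation.R`) walk the full
study — training and baselines, fusion, evaluation with permutation nulls
and paired t-tests, saliency, consensus subtyping, and decoding — writing
tables under `results/`.

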
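---
title: "Predicting severe aphasia and subtyping atrophy from morphometry and lesion maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting severe aphasia and subtyping atrophy from morphometry and lesion maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lesionsubtype)
```

## The analysis in one paragraph

Chronic post-stroke aphasia severity (the WAB-AQ, a 0-100 language score)
depends on lesion anatomy but also on the integrity of tissue far from the
stroke. This package implements, end to end, an analysis that (i) predicts
which stroke survivors have severe aphasia (WAB-AQ at or below 50) from a
single-channel ordinal morphometry map combining tissue segmentations and
the lesion, using a 3D convolutional network against tuned SVM baselines
under one preallocated repeated nested stratified cross-validation plan;
(ii) attributes the network's predictions to voxels with Grad-CAM++ and a
baseline-referenced path-gradient method, and the SVM's with kernel SHAP;
(iii) discovers atrophy subtypes by consensus clustering of saliency maps
under the eta-squared distance, with dip-test screening, PAC model-order
selection and affinity-propagation exemplars; and (iv) decodes exemplar
maps against chi-square meta-analytic topic maps. Because the real cohort
requires a controlled-access download, every component is exercised on a
synthetic cohort generator with planted ground truth.

## The synthetic cohort: what it emulates and what it does not

`cohort_spec()` / `generate_cohort()` build cohorts of template-registered
subjects. The template is an idealized mirror-symmetric brain (CSF shell,
grey-matter ribbon, white-matter core) on a common grid; each subject gets

* a **lesion**: a compact connected blob grown from a fixed
  perisylvian-analog seed point in the left hemisphere (an analog of
  middle-cerebral-artery territory strokes). For a given subject the growth
  order is fixed, so lesion volume is monotone in the size quantile; volume
  is capped at 25% of the left hemisphere;
* an **atrophy subtype**: one of K planted patterns, each a mixture of 2-4
  lobe-scale Gaussian blobs at well-separated grey-matter locations, some
  with a mirrored contralateral blob (bilateral patterns). Atrophy converts
  grey matter to CSF with probability `min(1, burden * pattern)`, where the
  subject-level burden is Gamma(3, 0.4) distributed;
* a **severity score**:
  `wab_aq = 97.5 - s * (lesion_effect * volume + atrophy_effect * burden) + N(0, noise_sd)`,
  clipped to [0, 100]. The common scale `s` is auto-calibrated by a
  monotone search so that the realized fraction with `wab_aq <= 50` lands
  within 5 percentage points of the 35% target prevalence.

Three design choices matter downstream and were fixed once:

* **Atrophy dominates severity.** With the defaults
  (`lesion_effect = 0.005`, `atrophy_effect = 40`) roughly 80% of the
  deficit variance comes from patterned atrophy and 20% from lesion volume.
  This mirrors the claim under study — that extralesional atrophy carries
  severity information beyond lesion size — and makes subtype-bearing signal
  present in the data by construction. Lesion size and subtype are drawn
  independently, so subgroups are not associated with lesion size.
* **Ceiling constant 97.5**, a near-maximum WAB-AQ for unimpaired speakers
  (any value in 95-100 would do; it is configurable).
* **All randomness flows from the single spec seed** through named
  substreams (one per subject and stage), so cohorts are bit-reproducible
  and individual subjects can be regenerated in isolation.

What the generator does **not** emulate: realistic neuroanatomy, scanner
noise, registration error, or morphometric variability outside the planted
patterns — every subject shares the template exactly. Passing tests
therefore show that the pipeline recovers structure *that is present*; they
do not show robustness to anatomical variability a real cohort would add.

## Ordinal morphometry maps

`compose_ordinal_map()` merges the three binary tissue masks and the lesion
into one grid of codes — background 0, CSF 1, GM 2, WM 3, lesion 4 — with
the lesion superseding any tissue. The CSF < GM < WM order follows tissue
density (the source material does not state the order; the code table is
configurable). `downsample_mode()` pools blocks by modal code — the block
analog of nearest-neighbour interpolation for label maps — with ties broken
toward the *highest* code so a lesion never vanishes on a tie; trailing
partial blocks pool over the available voxels. `crop_common_fov()` applies
the tightest cohort-common bounding box, and `scale_to_range()` maps code c
to `2c/4 - 1`. Modal pooling shrinks thin or surface-adjacent structures:
for interior spherical blobs of 200+ voxels the 8 mm volume stays within
±20% of the 2 mm volume / 64, but cortical lesions additionally lose rind
blocks to the background, which the tests check with a looser bound plus a
volume correlation.

## Cross-validation plan

`build_cv_plan()` preallocates 20 repeats (default) of 6 outer x 8 inner
stratified folds, shared by every model so paired comparisons across
repeats are equitable. Stratification uses the granular WAB-R categories —
very severe (0-25), severe (26-50), moderate (51-75), mild (76 and up);
scores strictly between 75 and 76 are treated as moderate, and the binary
severe label is `wab_aq <= 50` (inclusive, matching the category table).
Strata smaller than the fold count merge into the adjacent severity
category. Fold assignment shuffles within stratum and deals round-robin
with a rotation pointer carried across strata, which provably keeps overall
fold sizes within one subject and per-fold stratum counts within one of the
cohort proportions (231 subjects give test folds of 38/38/38/39/39/39).
`split_train_validation()` holds out `round(0.3 n)` subjects by
largest-remainder apportionment across strata — for a 192-subject outer
training set this gives 58 validation / 134 training (the printed "~135/~58"
cannot both hold exactly; the rounding convention is documented here).

## The 3D CNN

`build_cnn()` assembles a VGG-style network: blocks of 3x3x3 convolutions
(stride 1, padding 1, ReLU), each block followed by a 2x max-pool in ceiling
mode (an axis of size 1 passes through, since a ~24-voxel 8 mm input cannot
survive five strict halvings), then three fully connected layers — FC1 at
twice the final channel count with batch normalization and dropout
immediately after, FC2 back to the final channel count (the latent layer
read by `predict_and_latent()`), FC3 to the two classes. Four complexity
presets span 4-5 blocks, 1-4 convolutions per block and 8-128 channels; the
exact per-level layouts are this package's own (the source describes only
the ranges), and `channels`/`convs_per_block` accept explicit overrides.
Desk-scale examples use reduced two-block networks (`allow_small = TRUE`).

Training (`train_cnn()`) minimizes softmax cross entropy weighted by inverse
class frequencies, with stochastic gradient descent and classical momentum
0.9 — the source does not name its optimizer, and momentum-free SGD needs
impractically many epochs at these learning rates — under a cosine-annealing
schedule with warm restarts: `rate = floor + 0.5 (base - floor)(1 + cos(pi
t/T_i))`, first period 50 epochs, doubling at each restart (restarts at
cumulative epochs 50/150/350/750 over 800 epochs), floor 1e-10. The L2
penalty applies to weight matrices only (not biases or batch-norm
parameters). Early stopping watches validation loss with patience 100 and
minimum improvement 1e-4, restoring the best weights. Batch size 128 with
~135 training subjects means roughly one batch per epoch; it is implemented
as-is with per-epoch shuffling. The engine (forward and backward passes for
3D convolution via im2col matrix multiplication, ceiling-mode pooling,
batch normalization, dropout) is written in base R because no deep-learning
framework is available to R here and the network is itself the method under
study; its gradients are finite-difference-checked in the tests.

`tune_and_refit()` grid-searches configurations on the 8 inner folds using
the smallest *mean inner validation loss* (never accuracy) and refits the
winner on the outer training set with the stratified 70/30 split for early
stopping.

## SVM baselines

`fit_svm()` wraps the SMO solver in `e1071` (weighted hinge loss via
per-class costs); `random_search_svm()` draws candidates from 300
log-spaced bins per parameter (cost in [1e-3, 2e4], kernel scale in
[1e-3, 1e3], mapped to `gamma = 1/scale^2`), one value per bin without
replacement, 60 draws per fold by default (the draw count is not stated in
the source; 60 balances coverage and cost). Kernels are never tuned —
separate linear and radial models are fit. `fit_projection()` offers PCA
(SVD on the training matrix only) and ICA — a symmetric logcosh FastICA
applied to the retained PCA scores, keeping their dimensionality; ICA runs
on the tuned component count (whether the original used the tuned count or
the 75-component maximum is unknowable from the text). Class labels follow
the SVM decision sign; Platt-style probabilities (a logistic link fit on
internal out-of-sample decision values) exist because fusion consumes
probabilities.

## Fusion

`weighted_average_ensemble()` sweeps `p = w p_cnn + (1-w) p_svm` over 101
weights (step 0.01; the sweep granularity is a package choice). Endpoints
reproduce the individual models, and the maximum of the F1 curve can never
fall below the better endpoint. `stack_meta_learner()` fits an LDA over the
2D severe-probability space on training-fold predictions only (inner-fold
out-of-sample predictions in the pipeline, which prevents optimistic
stacking), with a ridge fallback for singular covariances.
`downstream_svm()` trains linear SVMs on CNN-derived features — latent FC2
activations or per-subject saliency maps — always generated by the fold
model under which the subject was in the *test* set, so the features carry
no leakage.

## Saliency

`grad_cam_pp()` weighs last-convolution channels by
`alpha = G^2 / (2 G^2 + sum_vox(A) G^3)` (the usual elementwise
gradient-power surrogate for the second- and third-order terms, exact for an
exponential-activated score; denominator epsilon-guarded), takes
`w_k = sum(alpha * relu(G))`, and upsamples `relu(sum_k w_k A_k)`
trilinearly to the input grid; maps are nonnegative by construction.
`deep_attribution()` is a baselines-averaged path-gradient (expected
gradients) estimator standing in for DeepLIFT-based deep SHAP: it preserves
the completeness property the downstream comparisons rely on (attributions
sum to the score difference from the baselines; 64 midpoint steps by
default, since 16 steps leave completeness errors of a few percent on ReLU
networks). The choice of baseline matters scientifically: against an
all-background volume, attribution magnitude tracks tissue *presence*
(atrophied voxels, being closer to background, receive *smaller*
attribution), whereas against the intact template map
(`template_ordinal_map()`) attribution localizes on each subject's
pathology — lesion and atrophy — which is what subtype clustering and
decoding need. The pipeline uses both the all-background volume and the
template reference as its baseline set. `kernel_shap()` solves the
Shapley-kernel weighted least squares over sampled coalitions with the
efficiency constraint eliminated analytically; absent features are imputed
from the instance's k nearest background neighbours (k = 10% of the
background). It enumerates all coalitions exactly when feasible and is
tested against brute-force Shapley values at up to 12 features; at voxel
dimension it is Monte-Carlo only. `build_rois()` forms lesion /
perilesional (1-voxel dilation ring by default) / extralesional partitions
of the left hemisphere and their sagittal-mirror homologues.

## Subtyping

The similarity between two maps is the eta-squared coefficient
`1 - SS_within/SS_total` computed pointwise, which penalizes scale *and*
offset differences (unlike Pearson correlation); the clustering distance is
`1 - eta2`. `kmeans_eta()` is k-means++ under this distance with
arithmetic-mean centroid updates (a relaxed k-means; medoid updates are
available), best of 250 restarts at full scale. `consensus_matrix()`
subsamples 60% of voxels per run (1000 runs at full scale) and records
co-clustering proportions over all subjects — the denominator is the run
count, since subjects are always present (the generic consensus definition
assumes subject resampling, but the procedure implemented here resamples
voxels, and the implementation follows the procedure). Solutions whose
consensus distributions are *consistent with unimodality* — Hartigan's dip
test fails to reject, p > 0.05 — are excluded; among the survivors the
largest k with PAC (fraction of consensus values strictly inside (0.1,
0.9)) at or below 0.1 is selected; all bounds configurable. The dip
statistic is implemented here (no R implementation is available in this
stack) by the iterative greatest-convex-minorant / least-concave-majorant
narrowing of the modal interval, and reproduces the known exact anchors
(0.25 for an equal two-point mixture, 1/(2n) for equally spaced samples);
p-values come from a uniform-reference bootstrap. Exemplars are extracted
by affinity propagation (damping 0.9, up to 2000 iterations, convergence =
100 iterations of a stable exemplar set, deterministic tie-breaking jitter
of 1e-8) with the shared preference bisected until the emergent cluster
count matches the selected k.

**What gets clustered.** Clustering operates on saliency maps restricted to
the *common non-lesioned field*: voxels lesioned in any subject of the
clustered class (union dilated by one voxel to cover the convolutional
halo) are dropped, and each map is normalized to unit sum
(`common_nonlesion_field()`, `saliency_feature_matrix()`). This choice was
forced by measurement, not taste: on synthetic cohorts, whole-grid
eta-squared distances between maps are dominated by lesion-anatomy
variance — planted subtypes are unrecoverable (adjusted Rand near 0) on
unmasked maps, while the same subjects' atrophy-change maps separate
perfectly. Masking only each subject's own lesion is insufficient, because
within any *pair* the other subject's lesion voxels still differ. On real
data, where every brain differs everywhere, the unrestricted variant may
behave differently; both are available.

**Which saliency gets clustered.** The pipeline's default clustering input
is Grad-CAM++ (`subtype_saliency = "grad_cam_pp"`), the method the subtype
analysis is built around at full scale. At desk scale, however,
Grad-CAM++ is structurally handicapped: its channel weights aggregate
gradients over space, so with a small network and template-shared anatomy
the between-subject CAM differences are dominated by lesion-halo activation
changes and channel-weight jitter multiplying the shared anatomy maps, not
by atrophy-pattern differences. Measured on planted-subtype cohorts,
CAM-based consensus clustering reaches adjusted Rand ~0.5-0.7 (occasionally
1.0, occasionally ~0.1), and no tested remedy — masking variants, cohort-mean
centering, wider channels, no dropout, full-resolution last convolutions,
longer training, or CAM ensembling — lifts it reliably. The
template-referenced path-gradient maps recover the same planted subtypes
with adjusted Rand near 1.0, so the desk-scale recovery demonstrations use
them (`subtype_saliency = "deep_attr"`). This is a documented scale
limitation of CAM-family attribution, not of the consensus machinery.

## Decoding

`simulate_topic_corpus()` emulates a topic-tagged neuroimaging literature:
400 studies (default), 200 topics, 5% baseline voxel activation, and
planted topic-pattern links that multiply activation odds by 8 inside a
pattern for member studies. `chi_square_meta_map()` forms the per-voxel 2x2
activation-by-membership table and reports `sign(observed - expected) *
sqrt(chi2)` without continuity correction (zero-margin voxels score 0) —
a signed association map, which is what a Pearson correlation against a
saliency map needs; whether the original correlated against z, p or
thresholded maps is not stated. `decode_saliency()` correlates the saliency
map with each topic map over non-lesion brain voxels and retains topics
with r > 0.2 *and* Bonferroni-corrected p < 1e-4 (the threshold is read as
a corrected-p bound: raw p times the number of topics, capped at 1).

## Orchestration and problem sizes

`run_experiment()` executes simulate → preprocess → plan → train → fuse →
evaluate → saliency → subtype → decode with per-stage RDS caching keyed by
the relevant configuration entries: reruns with an unchanged configuration
are no-ops, a changed upstream entry invalidates downstream stages, and a
corrupted intermediate raises an error rather than silently recomputing.
Two presets exist: `paper` (231 subjects, 20 repeats, 6x8 folds, 800
epochs, 500 permutations — a cluster-scale configuration) and `smoke` (60
subjects, 2 repeats, 2x2 folds, 50 epochs). The test suite and the analysis
scripts run reduced designs — cohorts of 24-120 subjects on 24-32 voxel
grids, two-block networks, 50-200 epochs, 60-120 consensus runs of 8-15
restarts, 20 permutations — chosen so the full suite completes on a single
CPU while still exercising every code path at sizes where the planted
structure is recoverable; all counts scale up by configuration alone.

## Numerical choices and degenerate inputs

Softmax is computed with max-subtraction; probabilities are floored at
1e-12 inside the loss. Batch normalization uses running statistics at
evaluation (momentum 0.1, epsilon 1e-5). The Grad-CAM++ denominator is
epsilon-guarded (1e-8) and all-zero gradients yield a zero map with a
warning rather than NaN. Kernel SHAP returns all-zero attributions for
constant predictors, flagged. Ties in modal pooling go to the highest code;
ties in k-means assignment to the first minimal centroid; empty k-means
clusters are reseeded to the farthest point. The dip test returns dip 0 and
p 1 for constant samples. Division-by-zero in confusion metrics yields 0
with a flag. `eta_squared_similarity()` refuses two constant maps, and
`normalize_saliency()` refuses maps that truncate to zero mass.

## Known limitations

The CNN engine is CPU-bound base R; full-scale (800-epoch, 231-subject)
training is hours, not minutes — the package is sized for desk-scale
synthetic experiments and for methodological scrutiny, not for training on
large real cohorts. Grad-CAM++ loses per-subject localization when networks
are very small and anatomy is shared across subjects (channel weights
aggregate over space); at desk scale the subtype-recovery results depend on
the common-field restriction described above. The dip implementation
follows the GCM/LCM narrowing construction and matches the known anchors,
but it is an independent reimplementation, not a port of the reference
Fortran. Affinity propagation's preference bisection returns the nearest
achievable cluster count, flagged, when the exact target is unreachable.
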
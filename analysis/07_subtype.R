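#!/usr/bin/env Rscript
# Discover atrophy subtypes: consensus clustering (eta-squared k-means over
# voxel subsamples) of saliency maps restricted to the common non-lesioned
# field, run per predicted class; dip screening + PAC selection; affinity-
# propagation exemplars; comparison against the planted subtypes.
#
# Saliency here comes from one dedicated network attributed against the
# intact-template reference: pooling attribution maps produced by different
# fold models mixes model-specific gradient structure into the distances and
# destroys subtype recovery at this scale (the per-fold maps from
# 06_saliency.R are kept for the ROI analysis, where only within-subject
# averages matter).
suppressPackageStartupMessages(library(lesionsubtype))

cohort <- readRDS("results/cohort.rds")
prep <- readRDS("results/prep.rds")
pl <- readRDS("results/plan.rds")
x <- prep$features
y <- as.integer(pl$labels$severe)
truth <- cohort$truth$true_subtype

sp <- split_train_validation(seq_along(y), 0.3, pl$labels$category, seed = 77L)
cfg <- cnn_config(channels = c(8L, 16L), convs_per_block = c(1L, 1L),
                  dropout_rate = 0.6, l2_penalty = 0.001,
                  base_learning_rate = 1e-2, input_shape = prep$dims,
                  allow_small = TRUE)
fit <- train_cnn(build_cnn(cfg, seed = 77L), x[sp$train, ], y[sp$train],
                 x[sp$validation, ], y[sp$validation],
                 training_schedule(total_epochs = 120L, batch_size = 32L,
                                   early_stop_patience = 120L), seed = 77L)
pred <- predict_and_latent(fit, x)$labels
cat(sprintf("attribution model: pooled F1 %.3f\n", confusion_metrics(y, pred)$f1))
bline <- as.numeric(template_ordinal_map(cohort$template, 4, prep$bbox)$values)

out <- list()
for (cls in c(1L, 0L)) {
  members <- which(pred == cls)
  if (length(members) < 10) next
  field <- common_nonlesion_field(x[members, , drop = FALSE], prep$dims)
  maps <- lapply(members, function(i)
    abs(deep_attribution(fit, x[i, ], cls, rbind(bline), m_steps = 16L)$values))
  gm <- saliency_feature_matrix(maps, field)
  ks <- 3:6
  cms <- lapply(ks, function(k)
    consensus_matrix(gm, k, n_runs = 100L, n_replicates = 10L, seed = 40L + k))
  sel <- select_solution(cms, seed = 5L)
  sol <- affinity_propagation_consensus(cms[[match(sel$k_selected, ks)]],
                                        sel$k_selected)
  sim <- cluster_similarity_summary(gm, sol$assignments)
  cat(sprintf("class %d (n=%d): k_selected = %d (PAC %.3f); within eta2 %.3f vs between %.3f\n",
              cls, length(members), sel$k_selected, sel$pac,
              sim$mean_within, sim$mean_between))
  cat(sprintf("  adjusted Rand vs planted subtypes: %.2f\n",
              mclust::adjustedRandIndex(sol$assignments, truth[members])))
  an <- summary(aov(cohort$truth$lesion_volume_voxels[members] ~
                      factor(sol$assignments)))[[1]]
  cat(sprintf("  lesion size by subgroup: F = %.2f, p = %.2f\n", an[1, 4], an[1, 5]))
  out[[as.character(cls)]] <- list(members = members, field = field,
                                   maps = maps, selection = sel, solution = sol)
}
saveRDS(out, "results/subtypes.rds")
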
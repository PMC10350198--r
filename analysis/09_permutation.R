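#!/usr/bin/env Rscript
# Label-permutation robustness check of the CNN on a separable cohort
# (desk-scale: 20 permutations; the full design uses 500). The model
# building and testing procedure is a 2-fold cross-fit scored on the pooled
# held-out predictions, which keeps the F1 estimate stable at this sample
# size.
suppressPackageStartupMessages(library(lesionsubtype))

co <- generate_cohort(cohort_spec(n_subjects = 60L, grid_shape = c(24L, 28L, 24L),
                                  noise_sd = 1, seed = 19L))
prep <- preprocess_cohort(co, 4)
x <- prep$features
y <- as.integer(granular_category(co$truth$wab_aq)$severe)
cfg <- cnn_config(channels = c(8L, 8L), convs_per_block = c(1L, 1L),
                  dropout_rate = 0.6, base_learning_rate = 1e-2,
                  input_shape = prep$dims, allow_small = TRUE)
sched <- training_schedule(total_epochs = 50L, batch_size = 32L,
                           early_stop_patience = 50L)
runner <- function(labels, seed) {
  set.seed(seed)
  folds <- sample(rep_len(1:2, 60))
  pred <- integer(60)
  for (f in 1:2) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(unique(labels[tr])) < 2) return(0)
    val <- tr[seq_len(max(2, round(0.3 * length(tr))))]
    trn <- setdiff(tr, val)
    fit <- train_cnn(build_cnn(cfg, seed = seed), x[trn, ], labels[trn],
                     x[val, ], labels[val], sched, seed = seed)
    pred[te] <- predict_and_latent(fit, x[te, , drop = FALSE])$labels
  }
  confusion_metrics(labels, pred)$f1
}
res <- permutation_test(runner, y, n_permutations = 20L, seed = 5L)
cat(sprintf("observed F1 %.3f | null max %.3f | p = %.4f\n",
            res$observed, max(res$null), res$p))
write.csv(data.frame(null_f1 = res$null), "results/permutation_null.csv",
          row.names = FALSE)
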
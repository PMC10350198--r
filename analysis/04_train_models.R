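#!/usr/bin/env Rscript
# Train and tune the 3D CNN and the linear SVM baseline on the shared plan,
# pooling outer-fold test predictions within each repeat.
suppressPackageStartupMessages(library(lesionsubtype))

cohort <- readRDS("results/cohort.rds")
prep <- readRDS("results/prep.rds")
pl <- readRDS("results/plan.rds")
x <- prep$features
y <- as.integer(pl$labels$severe)
plan <- pl$plan

cfg <- cnn_config(channels = c(8L, 16L), convs_per_block = c(1L, 1L),
                  dropout_rate = 0.6, l2_penalty = 0.001,
                  base_learning_rate = 1e-2, input_shape = prep$dims,
                  allow_small = TRUE)
sched <- training_schedule(total_epochs = 120L, batch_size = 32L,
                           early_stop_patience = 120L)

n <- length(y)
cnn_models <- list()
preds <- list(cnn = list(), svm = list())
for (r in seq_len(plan$n_repeats)) {
  p_cnn <- matrix(NA_real_, n, 2); p_svm <- matrix(NA_real_, n, 2)
  lab_svm <- integer(n)
  for (f in seq_len(plan$n_outer)) {
    test <- plan$repeats[[r]]$outer[[f]]
    train <- sort(setdiff(seq_len(n), test))
    tr <- tune_and_refit(x, y, plan, r, f, list(cfg), sched,
                         seed = 1000L + 10L * r + f)
    p_cnn[test, ] <- predict_and_latent(tr$trained, x[test, , drop = FALSE])$probs
    cnn_models[[paste(r, f)]] <- tr$trained
    rs <- random_search_svm(x, y, train, plan$repeats[[r]]$inner[[f]],
                            kernel = "linear", n_candidates = 12L,
                            seed = 2000L + 10L * r + f)
    sm <- fit_svm(x[train, ], y[train], rs$best_config, seed = 3000L + r)
    pr <- predict(sm, x[test, , drop = FALSE])
    p_svm[test, ] <- pr$probs
    lab_svm[test] <- pr$labels
  }
  preds$cnn[[r]] <- list(y_true = y, y_pred = max.col(p_cnn) - 1L, probs = p_cnn)
  preds$svm[[r]] <- list(y_true = y, y_pred = lab_svm, probs = p_svm)
  cat(sprintf("repeat %d: CNN F1 %.3f | SVM F1 %.3f\n", r,
              confusion_metrics(y, preds$cnn[[r]]$y_pred)$f1,
              confusion_metrics(y, preds$svm[[r]]$y_pred)$f1))
}
saveRDS(list(models = cnn_models, preds = preds), "results/models.rds")
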
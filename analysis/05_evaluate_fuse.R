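#!/usr/bin/env Rscript
# Score pooled predictions per repeat, compare models with paired t-tests,
# and sweep the CNN/SVM probability-averaging ensemble.
suppressPackageStartupMessages(library(lesionsubtype))

mods <- readRDS("results/models.rds")
rec_cnn <- evaluate_repeats(mods$preds$cnn)
rec_svm <- evaluate_repeats(mods$preds$svm)
perf <- rbind(cbind(model = "cnn", rec_cnn), cbind(model = "svm", rec_svm))
write.csv(perf, "results/performance.csv", row.names = FALSE)

cat("Median F1: CNN", median(rec_cnn$f1), "| SVM", median(rec_svm$f1), "\n")
cmp <- paired_compare(rec_cnn$f1, rec_svm$f1)
cat(sprintf("Paired t-test (F1, CNN - SVM): t(%d) = %.2f, p = %.3g, d = %.2f\n",
            cmp$df, cmp$t, cmp$p, cmp$d))

y <- mods$preds$cnn[[1]]$y_true
ens <- weighted_average_ensemble(mods$preds$cnn[[1]]$probs,
                                 mods$preds$svm[[1]]$probs, y)
write.csv(ens$curve, "results/ensemble_curve.csv", row.names = FALSE)
best <- ens$curve[which.max(ens$curve$f1), ]
cat(sprintf("Ensemble repeat 1: best F1 %.3f at CNN weight %.2f\n",
            best$f1, best$weight))
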
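#!/usr/bin/env Rscript
# Preallocate the repeated nested stratified cross-validation plan shared by
# every model (6 outer folds at full scale; 3 here for the desk-scale run,
# 2 repeats), stratified on the granular WAB-R severity categories.
suppressPackageStartupMessages(library(lesionsubtype))

cohort <- readRDS("results/cohort.rds")
labels <- granular_category(cohort$truth$wab_aq)
plan <- build_cv_plan(labels$category, n_repeats = 2L, n_outer = 3L,
                      n_inner = 3L, seed = 21L)
write_cv_plan(plan, "results/cv_plan.json")
saveRDS(list(plan = plan, labels = labels), "results/plan.rds")

cat(sprintf("%d repeats x %d outer folds (sizes %s), %d inner folds\n",
            plan$n_repeats, plan$n_outer,
            paste(sort(lengths(plan$repeats[[1]]$outer)), collapse = "/"),
            plan$n_inner))
cat(sprintf("Severe prevalence: %.2f\n", mean(labels$severe)))
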
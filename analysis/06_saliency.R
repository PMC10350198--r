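#!/usr/bin/env Rscript
# Attribute repeat-1 predictions to voxels: Grad-CAM++ and baseline-referenced
# path-gradient maps for every subject from the fold model under which that
# subject was in the test set; ROI contrast of normalized maps.
suppressPackageStartupMessages(library(lesionsubtype))

cohort <- readRDS("results/cohort.rds")
prep <- readRDS("results/prep.rds")
pl <- readRDS("results/plan.rds")
mods <- readRDS("results/models.rds")
x <- prep$features
plan <- pl$plan
n <- nrow(x)
# baselines: all-background plus the intact template reference
bg <- rbind(rep(-1, ncol(x)),
            as.numeric(template_ordinal_map(cohort$template, 4, prep$bbox)$values))

gc_maps <- vector("list", n); da_maps <- vector("list", n)
pred <- mods$preds$cnn[[1]]$y_pred
for (f in seq_len(plan$n_outer)) {
  fit <- mods$models[[paste(1, f)]]
  for (i in plan$repeats[[1]]$outer[[f]]) {
    gc_maps[[i]] <- grad_cam_pp(fit, x[i, ], class = pred[i])
    da_maps[[i]] <- deep_attribution(fit, x[i, ], pred[i], bg, m_steps = 16L)
  }
}
saveRDS(list(grad_cam = gc_maps, deep_attr = da_maps, pred = pred),
        "results/saliency.rds")

# ROI contrast on the template anatomy (lesions differ per subject)
tm <- cohort$template
rois <- lapply(seq_len(n), function(i) {
  les8 <- array(x[i, ] == 1, prep$dims)
  brain8 <- array(x[i, ] != -1, prep$dims)
  left8 <- brain8
  left8[(floor(prep$dims[1] / 2) + 1):prep$dims[1], , ] <- FALSE
  build_rois(les8 & left8, brain8, left8)
})
nmaps <- lapply(seq_len(n), function(i)
  normalize_saliency(gc_maps[[i]]$values))
rc <- roi_contrast(nmaps, rois, pred)
write.csv(rc, "results/roi_contrast.csv", row.names = FALSE)
print(rc[, c("roi", "mean_severe", "mean_nonsevere", "p")])
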
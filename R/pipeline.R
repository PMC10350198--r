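# End-to-end experiment orchestration: simulate -> preprocess -> plan ->
# train (CNN + SVM) -> fuse -> evaluate -> saliency -> subtype -> decode,
# with per-stage RDS caching keyed by a configuration hash so reruns with an
# unchanged configuration are no-ops and stale intermediates are refused.

#' Default experiment configuration
#'
#' Two scale presets: `"paper"` mirrors the full design (231 subjects, 20
#' repeats, 6 outer x 8 inner folds, 800 epochs -- cluster-scale) and
#' `"smoke"` is a desk-scale reduction (60 subjects, 2 repeats, 2x2 folds,
#' one CNN configuration, 50 epochs). Every count can be overridden.
#'
#' @param scale "smoke" or "paper"
#' @param ... named overrides of any configuration entry
#' @return configuration list
#' @export
experiment_config <- function(scale = c("smoke", "paper"), ...) {
  scale <- match.arg(scale)
  base <- list(
    scale = scale, seed = 1L,
    n_subjects = 60L, grid_shape = c(24L, 28L, 24L), voxel_size_mm = 2,
    severe_prevalence_target = 0.35, n_subtypes = 4L, noise_sd = 8,
    downsample_factor = 4L,
    n_repeats = 2L, n_outer = 2L, n_inner = 2L,
    cnn_grid = list(list(complexity_level = 1L, dropout_rate = 0.6,
                         l2_penalty = 0.001, base_learning_rate = 1e-4)),
    epochs = 50L, batch_size = 32L, patience = 50L,
    svm_kernel = "linear", svm_reduction = "none", svm_candidates = 8L,
    n_permutations = 0L,
    subtype_kmin = 2L, subtype_kmax = 6L, consensus_runs = 100L,
    consensus_replicates = 5L, subtype_saliency = "grad_cam_pp",
    n_topics = 40L, n_studies = 200L,
    allow_small_cnn = TRUE)
  if (scale == "paper") {
    base <- utils::modifyList(base, list(
      n_subjects = 231L, grid_shape = c(48L, 56L, 48L),
      n_repeats = 20L, n_outer = 6L, n_inner = 8L,
      cnn_grid = lapply(1:4, function(l) list(complexity_level = l,
                                              dropout_rate = 0.6,
                                              l2_penalty = 0.001,
                                              base_learning_rate = 1e-4)),
      epochs = 800L, batch_size = 128L, patience = 100L,
      svm_candidates = 60L, n_permutations = 500L,
      subtype_kmin = 3L, subtype_kmax = 30L, consensus_runs = 1000L,
      consensus_replicates = 250L, n_topics = 200L, n_studies = 400L,
      allow_small_cnn = FALSE))
  }
  utils::modifyList(base, list(...))
}

config_hash <- function(config, stage_fields) {
  sub <- config[sort(intersect(names(config), stage_fields))]
  paste(deparse(sub), collapse = "")
}

stage_cached <- function(out_dir, stage, hash, compute, log) {
  path <- file.path(out_dir, paste0(stage, ".rds"))
  if (file.exists(path)) {
    obj <- tryCatch(readRDS(path), error = function(e)
      stop_input("corrupted intermediate for stage '%s': delete %s to recompute",
                 stage, path))
    if (identical(obj$hash, hash)) {
      log(sprintf("stage %-10s cache hit", stage))
      return(obj$value)
    }
  }
  log(sprintf("stage %-10s computing", stage))
  value <- compute()
  saveRDS(list(hash = hash, value = value), path)
  value
}

cnn_grid_to_configs <- function(config, input_shape) {
  lapply(config$cnn_grid, function(g) {
    args <- utils::modifyList(g, list(input_shape = input_shape,
                                      allow_small = isTRUE(config$allow_small_cnn)))
    if (isTRUE(config$allow_small_cnn) && is.null(g$channels) &&
        identical(g$complexity_level, 1L) && config$scale == "smoke") {
      # desk-scale network: 2 blocks keep spatial resolution for saliency
      args$channels <- c(8L, 16L)
      args$convs_per_block <- c(1L, 1L)
    }
    do.call(cnn_config, args)
  })
}

run_cv_models <- function(x, y, plan, config, schedule, seed) {
  configs <- cnn_grid_to_configs(config, attr(x, "dims"))
  n <- length(y)
  cnn_models <- list(); svm_models <- list()
  preds <- list(cnn = list(), svm = list())
  for (r in seq_len(plan$n_repeats)) {
    p_cnn <- matrix(NA_real_, n, 2); p_svm <- matrix(NA_real_, n, 2)
    latent <- NULL
    for (f in seq_len(plan$n_outer)) {
      test <- plan$repeats[[r]]$outer[[f]]
      train <- sort(setdiff(seq_len(n), test))
      tr <- tune_and_refit(x, y, plan, r, f, configs, schedule,
                           seed = substream_seed(seed, "cnn", r, f))
      pl <- predict_and_latent(tr$trained, x)
      if (is.null(latent)) latent <- matrix(NA_real_, n, ncol(pl$latent))
      p_cnn[test, ] <- pl$probs[test, ]
      latent[test, ] <- pl$latent[test, ]
      rs <- random_search_svm(x, y, train, plan$repeats[[r]]$inner[[f]],
                              kernel = config$svm_kernel,
                              reduction = config$svm_reduction,
                              n_candidates = config$svm_candidates,
                              seed = substream_seed(seed, "svm", r, f))
      sm <- fit_svm(x[train, , drop = FALSE], y[train], rs$best_config,
                    seed = substream_seed(seed, "svmfit", r, f))
      p_svm[test, ] <- predict(sm, x[test, , drop = FALSE])$probs
      cnn_models[[paste(r, f)]] <- tr
      svm_models[[paste(r, f)]] <- sm
    }
    preds$cnn[[r]] <- list(y_true = y, y_pred = max.col(p_cnn) - 1L,
                           probs = p_cnn, latent = latent)
    preds$svm[[r]] <- list(y_true = y, y_pred = max.col(p_svm) - 1L,
                           probs = p_svm)
  }
  list(cnn_models = cnn_models, svm_models = svm_models, preds = preds)
}

#' Run the full experiment from one configuration
#'
#' Executes every stage in order, caching each stage's output under
#' `out_dir` keyed by the relevant configuration entries; reruns with an
#' unchanged configuration hit the cache, and a changed upstream entry
#' invalidates all downstream stages.
#'
#' @param config a configuration list from [experiment_config()], or a path
#'   to a YAML file of overrides
#' @param out_dir results directory
#' @return invisible list of all stage outputs
#' @export
run_experiment <- function(config = experiment_config(), out_dir) {
  if (is.character(config)) {
    config <- do.call(experiment_config, yaml::read_yaml(config))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log <- function(msg) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
                           file = log_path, append = TRUE)
  jsonlite::write_json(list(config = config[order(names(config))],
                            package_version = as.character(utils::packageVersion("lesionsubtype"))),
                       file.path(out_dir, "provenance.json"), auto_unbox = TRUE,
                       digits = NA)

  sim_fields <- c("seed", "n_subjects", "grid_shape", "voxel_size_mm",
                  "severe_prevalence_target", "n_subtypes", "noise_sd")
  cohort <- stage_cached(out_dir, "simulate", config_hash(config, sim_fields),
                         function() generate_cohort(do.call(cohort_spec,
                           config[sim_fields])), log)

  pre_fields <- c(sim_fields, "downsample_factor")
  prep <- stage_cached(out_dir, "preprocess", config_hash(config, pre_fields),
                       function() preprocess_cohort(cohort, config$downsample_factor),
                       log)
  x <- prep$features
  attr(x, "dims") <- prep$dims
  labels <- granular_category(cohort$truth$wab_aq)
  y <- as.integer(labels$severe)

  plan_fields <- c(pre_fields, "n_repeats", "n_outer", "n_inner")
  plan <- stage_cached(out_dir, "plan", config_hash(config, plan_fields),
                       function() build_cv_plan(labels$category, config$n_repeats,
                                                config$n_outer, config$n_inner,
                                                seed = substream_seed(config$seed, "plan")),
                       log)

  train_fields <- c(plan_fields, "cnn_grid", "epochs", "batch_size", "patience",
                    "svm_kernel", "svm_reduction", "svm_candidates")
  schedule <- training_schedule(total_epochs = config$epochs,
                                batch_size = config$batch_size,
                                early_stop_patience = config$patience)
  trained <- stage_cached(out_dir, "train", config_hash(config, train_fields),
                          function() run_cv_models(x, y, plan, config, schedule,
                                                   substream_seed(config$seed, "train")),
                          log)

  fuse <- stage_cached(out_dir, "fuse", config_hash(config, train_fields),
                       function() {
    lapply(seq_len(plan$n_repeats), function(r) {
      ens <- weighted_average_ensemble(trained$preds$cnn[[r]]$probs,
                                       trained$preds$svm[[r]]$probs, y)
      list(curve = ens$curve, best_f1 = max(ens$curve$f1))
    })
  }, log)

  evals <- stage_cached(out_dir, "evaluate", config_hash(config, train_fields),
                        function() {
    rec_cnn <- evaluate_repeats(trained$preds$cnn)
    rec_svm <- evaluate_repeats(trained$preds$svm)
    cmp <- if (plan$n_repeats >= 2)
      tryCatch(paired_compare(rec_cnn$f1, rec_svm$f1), error = function(e) NULL)
    list(cnn = rec_cnn, svm = rec_svm, paired_f1 = cmp)
  }, log)

  sal_fields <- train_fields
  sal <- stage_cached(out_dir, "saliency", config_hash(config, sal_fields),
                      function() {
    # maps come from the repeat-1 fold model under which the subject was in
    # the test set, so no subject is attributed by a model that trained on it
    r <- 1L
    gc_maps <- vector("list", length(y)); da_maps <- vector("list", length(y))
    pred_class <- integer(length(y))
    # baselines: all-background plus the intact template reference
    bg <- rbind(rep(-1, ncol(prep$features)),
                as.numeric(template_ordinal_map(cohort$template,
                                                config$downsample_factor,
                                                prep$bbox)$values))
    for (f in seq_len(plan$n_outer)) {
      test <- plan$repeats[[r]]$outer[[f]]
      mod <- trained$cnn_models[[paste(r, f)]]$trained
      for (i in test) {
        cls <- trained$preds$cnn[[r]]$y_pred[i]
        pred_class[i] <- cls
        gc_maps[[i]] <- grad_cam_pp(mod, x[i, ], class = cls)
        da_maps[[i]] <- deep_attribution(mod, x[i, ], cls, bg)
      }
    }
    list(grad_cam = gc_maps, deep_attr = da_maps, pred_class = pred_class)
  }, log)

  sub_fields <- c(sal_fields, "subtype_kmin", "subtype_kmax", "consensus_runs",
                  "consensus_replicates", "subtype_saliency")
  subty <- stage_cached(out_dir, "subtype", config_hash(config, sub_fields),
                        function() {
    per_class <- list()
    for (cls in c(1L, 0L)) {
      members <- which(sal$pred_class == cls)
      if (length(members) < max(8, config$subtype_kmin + 2)) next
      field <- common_nonlesion_field(x[members, , drop = FALSE], prep$dims)
      src <- if (identical(config$subtype_saliency, "deep_attr"))
        lapply(sal$deep_attr[members], function(m) abs(m$values))
      else sal$grad_cam[members]
      gm <- saliency_feature_matrix(src, field)
      ks <- config$subtype_kmin:min(config$subtype_kmax, length(members) - 2L)
      cms <- lapply(ks, function(k)
        consensus_matrix(gm, k, n_runs = config$consensus_runs,
                         n_replicates = config$consensus_replicates,
                         seed = substream_seed(config$seed, "consensus", cls, k)))
      selection <- select_solution(cms, seed = substream_seed(config$seed, "select", cls))
      sol <- affinity_propagation_consensus(
        cms[[match(selection$k_selected, ks)]], selection$k_selected)
      per_class[[as.character(cls)]] <- list(members = members,
                                             selection = selection, solution = sol)
    }
    per_class
  }, log)

  dec_fields <- c(sub_fields, "n_topics", "n_studies")
  decoding <- stage_cached(out_dir, "decode", config_hash(config, dec_fields),
                           function() {
    # topic maps live on the downsampled grid; plant each subtype pattern
    brain8 <- array(prep$maps[[1]]$values != -1, prep$dims)
    planted <- stats::setNames(
      lapply(seq_along(cohort$patterns), function(s) {
        dm <- downsample_mode(new_ordinal_map(
          (cohort$patterns[[s]] > 0.5) * 4, cohort$spec$voxel_size_mm),
          config$downsample_factor)
        cr <- dm$values[prep$bbox[1, 1]:prep$bbox[2, 1],
                        prep$bbox[1, 2]:prep$bbox[2, 2],
                        prep$bbox[1, 3]:prep$bbox[2, 3], drop = FALSE]
        (cr == 4) * 1
      }), as.character(seq_along(cohort$patterns)))
    corpus <- simulate_topic_corpus(brain8, n_studies = config$n_studies,
                                    n_topics = config$n_topics,
                                    planted = planted,
                                    seed = substream_seed(config$seed, "corpus"))
    topic_maps <- lapply(seq_len(config$n_topics),
                         function(t) chi_square_meta_map(corpus, t))
    rankings <- list()
    for (cls in names(subty)) {
      sol <- subty[[cls]]$solution
      members <- subty[[cls]]$members
      for (e in seq_along(sol$exemplars)) {
        ex_subj <- members[sol$exemplars[e]]
        lesion8 <- array(prep$maps[[ex_subj]]$values == 1, prep$dims)
        rk <- decode_saliency(sal$grad_cam[[ex_subj]]$values, lesion8,
                              topic_maps, brain8)
        rankings[[paste0("class", cls, "_cluster", e)]] <-
          list(exemplar_subject = ex_subj, ranking = utils::head(rk, 10))
      }
    }
    list(rankings = rankings)
  }, log)

  out <- list(cohort_truth = cohort$truth, plan = plan, evaluation = evals,
              fusion = fuse, subtyping = subty, decoding = decoding,
              config = config)
  invisible(out)
}

#' Summarize a results directory into report tables
#'
#' @param out_dir directory previously populated by [run_experiment()]
#' @return list of tables; also writes CSV files and a markdown report under
#'   `out_dir`
#' @export
summarize_results <- function(out_dir) {
  read_stage <- function(stage) {
    path <- file.path(out_dir, paste0(stage, ".rds"))
    if (!file.exists(path)) return(NULL)
    readRDS(path)$value
  }
  evals <- read_stage("evaluate")
  if (is.null(evals)) stop_input("no evaluation outputs in %s", out_dir)
  perf <- rbind(cbind(model = "cnn", evals$cnn), cbind(model = "svm", evals$svm))
  utils::write.csv(perf, file.path(out_dir, "performance.csv"), row.names = FALSE)
  long <- stats::reshape(perf, direction = "long",
                         varying = list(c("acc_severe", "acc_nonsevere",
                                          "balanced_accuracy", "precision",
                                          "recall", "f1")),
                         v.names = "value", timevar = "metric",
                         times = c("acc_severe", "acc_nonsevere",
                                   "balanced_accuracy", "precision", "recall", "f1"))
  utils::write.csv(long, file.path(out_dir, "performance_long.csv"), row.names = FALSE)
  fuse <- read_stage("fuse")
  subty <- read_stage("subtype")
  decoding <- read_stage("decode")
  md <- c("# Experiment summary", "",
          "## Model performance (per repeat, pooled outer folds)", "",
          utils::capture.output(print(stats::aggregate(
            f1 ~ model, perf, function(v) c(median = stats::median(v))))))
  if (!is.null(evals$paired_f1))
    md <- c(md, "", sprintf("Paired t-test on F1 (df = %d): t = %.2f, p = %.3g, d = %.2f",
                            evals$paired_f1$df, evals$paired_f1$t,
                            evals$paired_f1$p, evals$paired_f1$d))
  if (!is.null(fuse))
    md <- c(md, "", sprintf("Ensemble best F1 (repeat 1): %.3f", fuse[[1]]$best_f1))
  if (!is.null(subty) && length(subty)) {
    for (cls in names(subty))
      md <- c(md, sprintf("Subtyping class %s: k = %d (PAC %.3f)", cls,
                          subty[[cls]]$selection$k_selected,
                          subty[[cls]]$selection$pac))
  } else md <- c(md, "", "Subtyping: absent")
  md <- c(md, "", if (is.null(decoding)) "Decoding: absent" else
    sprintf("Decoding: %d exemplar rankings", length(decoding$rankings)))
  writeLines(md, file.path(out_dir, "report.md"))
  list(performance = perf, performance_long = long,
       paired_f1 = evals$paired_f1, report = md)
}
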
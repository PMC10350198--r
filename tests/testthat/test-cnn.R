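test_that("inverse-frequency class weights follow the formula", {
  w <- class_weights(c(rep(1, 35), rep(0, 65)))
  expect_equal(unname(w["1"]), 1 / 0.35)
  expect_equal(unname(w["0"]), 1 / 0.65)
  wb <- class_weights(c(0, 0, 1, 1))
  expect_equal(unname(wb["0"]), unname(wb["1"]))
  expect_error(class_weights(c(1, 1, 1)), "single class")
})

test_that("warm-restart schedule matches its closed form over all 800 epochs", {
  s <- training_schedule()
  base <- 1e-4
  boundaries <- c(50, 150, 350, 750)
  periods <- c(50, 100, 200, 400, 800)
  starts <- c(0, boundaries)
  dev <- vapply(0:799, function(epoch) {
    cyc <- findInterval(epoch, starts)
    t <- epoch - starts[cyc]
    expected <- 1e-10 + 0.5 * (base - 1e-10) * (1 + cos(pi * t / periods[cyc]))
    abs(cosine_warm_restart_rate(epoch, s, base) - expected)
  }, numeric(1))
  expect_lt(max(dev), 1e-18)
  # restarts return to the base rate; cycle ends approach the floor
  for (b in boundaries) {
    expect_equal(cosine_warm_restart_rate(b, s, base), base)
    expect_lt(cosine_warm_restart_rate(b - 1, s, base), 1e-6)
  }
  expect_equal(cosine_warm_restart_rate(0, s, base), base)
})

test_that("complexity presets build the documented architectures", {
  cfg <- cnn_config(1, input_shape = c(12L, 14L, 12L))
  m <- build_cnn(cfg)
  types <- vapply(m$layers, `[[`, "", "type")
  convs <- which(types == "conv")
  expect_length(convs, 4)
  expect_equal(vapply(convs, function(i) m$layers[[i]]$C_out, numeric(1)),
               c(8, 16, 32, 64))
  expect_length(which(types == "pool"), 4)
  denses <- which(types == "dense")
  expect_equal(ncol(m$layers[[denses[1]]]$W), 128)   # FC1 = 2 x C_last
  expect_equal(ncol(m$layers[[denses[2]]]$W), 64)    # FC2 = latent
  expect_equal(ncol(m$layers[[denses[3]]]$W), 2)     # FC3 = classes
  expect_equal(m$latent_width, 64)
  expect_error(cnn_config(channels = c(4, 8, 16, 32), input_shape = c(8L, 8L, 8L)),
               "within")
  expect_error(cnn_config(channels = c(8, 16), input_shape = c(8L, 8L, 8L)),
               "blocks")
})

test_that("forward pass yields probabilities and a zero L2 term at zero weights", {
  cfg <- cnn_config(channels = c(8L, 8L), convs_per_block = c(1L, 1L),
                    input_shape = c(6L, 6L, 6L), allow_small = TRUE)
  m <- build_cnn(cfg, seed = 3)
  x <- matrix(rnorm(2 * 216), 2)
  fw <- lesionsubtype:::nn_forward(m, x)
  expect_equal(rowSums(fw$probs), c(1, 1), tolerance = 1e-6)
  m0 <- m
  for (i in seq_along(m0$layers))
    if (m0$layers[[i]]$type %in% c("conv", "dense"))
      m0$layers[[i]]$W[] <- 0
  expect_equal(lesionsubtype:::l2_penalty_value(m0), 0)
})

test_that("weighted loss scales the unweighted loss by a constant on balanced data", {
  probs <- matrix(c(0.7, 0.3, 0.2, 0.8, 0.6, 0.4, 0.1, 0.9), 4, 2, byrow = TRUE)
  y <- c(0L, 1L, 0L, 1L)
  l1 <- lesionsubtype:::weighted_ce_loss(probs, y, c(1, 1))$loss
  l2 <- lesionsubtype:::weighted_ce_loss(probs, y, c(2, 2))$loss
  expect_equal(l2, 2 * l1)
})

test_that("inverse-frequency weighting equals minority duplication up to a constant", {
  # two majority points, one minority point; duplicating the minority until
  # balance and using flat weights must be proportional to the weighted loss
  probs <- matrix(c(0.8, 0.2, 0.6, 0.4, 0.3, 0.7), 3, 2, byrow = TRUE)
  y <- c(0L, 0L, 1L)
  w <- as.numeric(class_weights(y))                 # (1.5, 3)
  weighted <- lesionsubtype:::weighted_ce_loss(probs, y, w)$loss
  probs_dup <- rbind(probs, probs[3, ])
  y_dup <- c(y, 1L)
  duplicated <- lesionsubtype:::weighted_ce_loss(probs_dup, y_dup, c(1, 1))$loss
  expect_equal(weighted / duplicated, 2, tolerance = 1e-12)
})

test_that("training fits a separable fixture and is reproducible", {
  tt <- tiny_trained()
  rec <- confusion_metrics(tt$y[tt$train],
                           predict_and_latent(tt$fit, tt$x[tt$train, ])$labels)
  expect_gte(rec$f1, 0.95)
  # latent features have the configured width; predictions are reproducible
  p1 <- predict_and_latent(tt$fit, tt$x[tt$val, ])
  p2 <- predict_and_latent(tt$fit, tt$x[tt$val, ])
  expect_identical(p1$probs, p2$probs)
  expect_equal(ncol(p1$latent), tt$fit$latent_width)
  expect_identical(p1$labels, max.col(p1$probs) - 1L)
})

test_that("identical seeds reproduce the training trajectory exactly", {
  tt <- tiny_trained()
  cfg <- cnn_config(channels = c(8L, 8L), convs_per_block = c(1L, 1L),
                    dropout_rate = 0.6, base_learning_rate = 1e-2,
                    input_shape = tt$dims, allow_small = TRUE)
  sched <- training_schedule(total_epochs = 15L, batch_size = 32L,
                             early_stop_patience = 15L)
  f1 <- train_cnn(build_cnn(cfg, seed = 5), tt$x[tt$train, ], tt$y[tt$train],
                  tt$x[tt$val, ], tt$y[tt$val], sched, seed = 5)
  f2 <- train_cnn(build_cnn(cfg, seed = 5), tt$x[tt$train, ], tt$y[tt$train],
                  tt$x[tt$val, ], tt$y[tt$val], sched, seed = 5)
  expect_equal(f1$best_val_loss, f2$best_val_loss, tolerance = 1e-12)
  expect_identical(f1$training_log, f2$training_log)
})

test_that("permuted labels keep validation performance in the chance band", {
  tt <- tiny_trained()
  cfg <- cnn_config(channels = c(8L, 8L), convs_per_block = c(1L, 1L),
                    dropout_rate = 0.6, base_learning_rate = 1e-2,
                    input_shape = tt$dims, allow_small = TRUE)
  sched <- training_schedule(total_epochs = 40L, batch_size = 32L,
                             early_stop_patience = 40L)
  set.seed(17)
  yp <- sample(tt$y)
  fit <- train_cnn(build_cnn(cfg, seed = 2), tt$x[tt$train, ], yp[tt$train],
                   tt$x[tt$val, ], yp[tt$val], sched, seed = 2)
  bal <- confusion_metrics(yp[tt$val],
                           predict_and_latent(fit, tt$x[tt$val, ])$labels)$balanced_accuracy
  expect_gte(bal, 0.25)
  expect_lte(bal, 0.75)
})

test_that("nested tuning selects by mean inner loss and prefers informative models", {
  tt <- tiny_trained()
  strata <- granular_category(tiny_cohort()$truth$wab_aq)$category
  plan <- build_cv_plan(strata, n_repeats = 1, n_outer = 2, n_inner = 2, seed = 3)
  sched <- training_schedule(total_epochs = 25L, batch_size = 32L,
                             early_stop_patience = 25L)
  single <- list(cnn_config(channels = c(8L, 8L), convs_per_block = c(1L, 1L),
                            dropout_rate = 0.6, base_learning_rate = 1e-2,
                            input_shape = tt$dims, allow_small = TRUE))
  res <- tune_and_refit(tt$x, tt$y, plan, 1, 1, single, sched, seed = 4)
  expect_identical(res$config, single[[1]])
  expect_true(all(res$tuning_log$criterion == "mean_inner_loss"))
  # a candidate that cannot learn (frozen zero rate) loses to a working one
  grid <- list(cnn_config(channels = c(8L, 8L), convs_per_block = c(1L, 1L),
                          dropout_rate = 0.6, base_learning_rate = 1e-2,
                          input_shape = tt$dims, allow_small = TRUE),
               cnn_config(channels = c(8L, 8L), convs_per_block = c(1L, 1L),
                          dropout_rate = 0.8, base_learning_rate = 1e-12,
                          input_shape = tt$dims, allow_small = TRUE))
  res2 <- tune_and_refit(tt$x, tt$y, plan, 1, 1, grid, sched, seed = 4)
  expect_identical(res2$config, grid[[1]])
})
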
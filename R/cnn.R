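#' Configure a VGG-style 3D CNN
#'
#' Four complexity presets cover the tuned range: blocks of 3x3x3
#' convolutions (stride 1, padding 1, ReLU) each followed by a 2x max-pool
#' (ceiling mode, so an axis of size 1 passes through), terminated by three
#' fully connected layers: FC1 doubles the last convolutional channel count
#' (with batch normalization and dropout immediately after), FC2 halves it
#' back (the latent layer), FC3 outputs class probabilities.
#'
#' Presets: level 1 = 4 blocks x 1 conv, channels 8/16/32/64;
#' level 2 = 4 blocks x 2 convs, 16/32/64/128;
#' level 3 = 5 blocks x 2 convs, 8/16/32/64/128;
#' level 4 = 5 blocks with 2/2/3/3/4 convs, 8/16/32/64/128.
#' `channels` and `convs_per_block` may be given explicitly to override the
#' preset (they must stay within 8-128 channels, 1-4 convs, 4-5 blocks
#' unless `allow_small = TRUE`, which permits reduced desk-scale networks).
#'
#' @param complexity_level integer 1-4 selecting a preset
#' @param dropout_rate dropout frequency, one of 0.6, 0.7, 0.8
#' @param l2_penalty L2-norm penalty on weight parameters
#' @param base_learning_rate peak learning rate fed to the scheduler
#' @param n_classes number of output classes
#' @param input_shape 3 voxel counts of the (downsampled, cropped) input map
#' @param channels,convs_per_block optional explicit architecture
#' @param allow_small allow architectures below the preset bounds
#' @return object of class `cnn_config`
#' @export
cnn_config <- function(complexity_level = 1L, dropout_rate = 0.6,
                       l2_penalty = 0.001, base_learning_rate = 1e-4,
                       n_classes = 2L, input_shape,
                       channels = NULL, convs_per_block = NULL,
                       allow_small = FALSE) {
  presets <- list(
    list(channels = c(8, 16, 32, 64), convs = c(1, 1, 1, 1)),
    list(channels = c(16, 32, 64, 128), convs = c(2, 2, 2, 2)),
    list(channels = c(8, 16, 32, 64, 128), convs = c(2, 2, 2, 2, 2)),
    list(channels = c(8, 16, 32, 64, 128), convs = c(2, 2, 3, 3, 4))
  )
  if (is.null(channels)) {
    p <- presets[[complexity_level]]
    channels <- p$channels
    convs_per_block <- p$convs
  }
  if (is.null(convs_per_block)) convs_per_block <- rep(1L, length(channels))
  if (!allow_small) {
    if (any(channels < 8 | channels > 128))
      stop_input("channels per layer must lie within [8, 128]")
    if (length(channels) < 4 || length(channels) > 5)
      stop_input("blocks must lie within [4, 5]")
    if (any(convs_per_block < 1 | convs_per_block > 4))
      stop_input("convolutional layers per block must lie within [1, 4]")
  }
  structure(list(complexity_level = complexity_level, dropout_rate = dropout_rate,
                 l2_penalty = l2_penalty, base_learning_rate = base_learning_rate,
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 channels = as.integer(channels),
                 convs_per_block = as.integer(convs_per_block)),
            class = "cnn_config")
}

#' Training schedule with cosine annealing and warm restarts
#'
#' Defaults follow the training recipe: 800 epochs, mini-batches of 128,
#' a first annealing period of 50 epochs doubling at each restart (restart
#' boundaries at cumulative epochs 50, 150, 350, 750), a floor rate of
#' 1e-10, and early stopping on validation loss.
#'
#' @param total_epochs,batch_size,restart_period_0,period_multiplier,floor_rate
#'   schedule constants
#' @param early_stop_patience epochs without validation improvement tolerated
#' @param min_delta minimal validation-loss improvement that resets patience
#' @param class_weights optional per-class weights (else inverse frequencies)
#' @return object of class `training_schedule`
#' @export
training_schedule <- function(total_epochs = 800L, batch_size = 128L,
                              restart_period_0 = 50L, period_multiplier = 2,
                              floor_rate = 1e-10, early_stop_patience = 100L,
                              min_delta = 1e-4, class_weights = NULL) {
  structure(list(total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 restart_period_0 = as.integer(restart_period_0),
                 period_multiplier = period_multiplier,
                 floor_rate = floor_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, class_weights = class_weights),
            class = "training_schedule")
}

#' Inverse-class-frequency weights
#'
#' @param labels vector of class labels (both classes must be present)
#' @return named numeric vector, `weight_c = 1 / frequency_c`
#' @export
class_weights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2) stop_input("labels contain a single class; weights undefined")
  freq <- as.numeric(tab) / length(labels)
  stats::setNames(1 / freq, names(tab))
}

#' Cosine-annealed learning rate with warm restarts
#'
#' `rate = floor + 0.5*(base - floor)*(1 + cos(pi * t / T_i))` where `t`
#' counts epochs since the last restart and `T_i` is the current period
#' (`restart_period_0 * period_multiplier^i`). With defaults the restarts
#' fall at cumulative epochs 50, 150, 350, 750.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < total_epochs`
#' @param schedule a [training_schedule()]
#' @param base_rate peak learning rate
#' @return learning rate at `epoch`
#' @export
cosine_warm_restart_rate <- function(epoch, schedule, base_rate) {
  stopifnot(epoch >= 0)
  t <- epoch
  Ti <- schedule$restart_period_0
  while (t >= Ti) {
    t <- t - Ti
    Ti <- Ti * schedule$period_multiplier
  }
  schedule$floor_rate +
    0.5 * (base_rate - schedule$floor_rate) * (1 + cos(pi * t / Ti))
}

#' Build an untrained CNN from a configuration
#'
#' @param config a [cnn_config()]
#' @param seed seed for weight initialization
#' @return list with `layers`, bookkeeping indices and the `config`
#' @export
build_cnn <- function(config, seed = 1L) {
  with_seed(substream_seed(seed, "init"), {
    dm <- config$input_shape
    layers <- list()
    C_in <- 1L
    for (b in seq_along(config$channels)) {
      if (any(dm < 1))
        stop_input("spatial dimension collapsed to zero before block %d", b)
      for (j in seq_len(config$convs_per_block[b])) {
        layers[[length(layers) + 1L]] <- layer_conv(dm, C_in, config$channels[b])
        C_in <- config$channels[b]
        layers[[length(layers) + 1L]] <- list(type = "relu_conv")
      }
      pc <- pool_index_cache(dm)
      layers[[length(layers) + 1L]] <- list(type = "pool", dims = dm,
                                            idx8 = pc$idx8, dims_out = pc$dims_out)
      dm <- pc$dims_out
    }
    last_conv_index <- length(layers) - 1L   # relu after the final conv
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    C_last <- config$channels[length(config$channels)]
    n_flat <- prod(dm) * C_last
    layers[[length(layers) + 1L]] <- layer_dense(n_flat, 2L * C_last)
    layers[[length(layers) + 1L]] <- layer_batchnorm(2L * C_last)
    layers[[length(layers) + 1L]] <- list(type = "dropout", rate = config$dropout_rate)
    layers[[length(layers) + 1L]] <- list(type = "relu")
    layers[[length(layers) + 1L]] <- layer_dense(2L * C_last, C_last)
    layers[[length(layers) + 1L]] <- list(type = "relu")
    latent_index <- length(layers)           # FC2 activations: the latent layer
    layers[[length(layers) + 1L]] <- layer_dense(C_last, config$n_classes)
    list(layers = layers, input_shape = config$input_shape, config = config,
         latent_index = as.integer(latent_index),
         last_conv_index = as.integer(last_conv_index),
         latent_width = C_last)
  })
}

# class-weighted softmax cross entropy; labels are 0/1 (or 0..K-1)
weighted_ce_loss <- function(probs, labels, weights) {
  n <- nrow(probs)
  idx <- cbind(seq_len(n), labels + 1L)
  w <- weights[labels + 1L]
  p <- pmax(probs[idx], 1e-12)
  loss <- mean(w * (-log(p)))
  onehot <- matrix(0, n, ncol(probs))
  onehot[idx] <- 1
  dlogits <- (probs - onehot) * (w / n)
  list(loss = loss, dlogits = dlogits)
}

# L2 penalty over weight matrices only (not biases, not batch-norm params)
l2_penalty_value <- function(model) {
  s <- 0
  for (L in model$layers)
    if (L$type %in% c("conv", "dense")) s <- s + sum(L$W^2)
  s
}

# SGD with classical momentum; the L2 penalty acts on weight matrices only
sgd_step <- function(model, grads, lr, l2, vel, momentum = 0.9) {
  for (li in seq_along(model$layers)) {
    L <- model$layers[[li]]
    g <- grads[[li]]
    if (is.null(g)) next
    if (is.null(vel[[li]])) vel[[li]] <- lapply(g, function(x) 0 * x)
    if (L$type %in% c("conv", "dense")) {
      vel[[li]]$W <- momentum * vel[[li]]$W - lr * (g$W + 2 * l2 * L$W)
      vel[[li]]$b <- momentum * vel[[li]]$b - lr * g$b
      model$layers[[li]]$W <- L$W + vel[[li]]$W
      model$layers[[li]]$b <- L$b + vel[[li]]$b
    } else if (L$type == "batchnorm") {
      vel[[li]]$gamma <- momentum * vel[[li]]$gamma - lr * g$gamma
      vel[[li]]$beta <- momentum * vel[[li]]$beta - lr * g$beta
      model$layers[[li]]$gamma <- L$gamma + vel[[li]]$gamma
      model$layers[[li]]$beta <- L$beta + vel[[li]]$beta
    }
  }
  list(model = model, vel = vel)
}

#' Train a CNN with warm-restart SGD and early stopping
#'
#' Minimizes class-weighted cross entropy by plain stochastic gradient
#' descent under the cosine warm-restart schedule; keeps the weights from
#' the epoch with the best validation loss and stops early once the
#' validation loss has not improved by `min_delta` for
#' `early_stop_patience` epochs.
#'
#' @param model output of [build_cnn()]
#' @param x_train,y_train training maps (subjects x voxels) and 0/1 labels
#' @param x_val,y_val validation set, disjoint from training
#' @param schedule a [training_schedule()]
#' @param seed seed controlling shuffling and dropout
#' @return object of class `trained_cnn` with the fitted model, the config,
#'   `latent_width` and a per-epoch `training_log`
#' @export
train_cnn <- function(model, x_train, y_train, x_val, y_val, schedule, seed = 1L) {
  weights <- schedule$class_weights
  if (is.null(weights)) weights <- class_weights(y_train)
  weights <- as.numeric(weights)
  n <- nrow(x_train)
  l2 <- model$config$l2_penalty
  base_rate <- model$config$base_learning_rate
  best <- list(loss = Inf, layers = model$layers, epoch = -1L)
  log <- data.frame(epoch = integer(0), lr = numeric(0),
                    train_loss = numeric(0), val_loss = numeric(0))
  wait <- 0L
  vel <- vector("list", length(model$layers))
  with_seed(substream_seed(seed, "train"), {
    for (epoch in seq_len(schedule$total_epochs) - 1L) {
      lr <- cosine_warm_restart_rate(epoch, schedule, base_rate)
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = schedule$batch_size)) {
        bi <- ord[start:min(start + schedule$batch_size - 1L, n)]
        fw <- nn_forward(model, x_train[bi, , drop = FALSE], train = TRUE)
        model <- fw$model    # running batch-norm statistics
        ls <- weighted_ce_loss(fw$probs, y_train[bi], weights)
        if (!is.finite(ls$loss))
          stop_input("training diverged (non-finite loss) at epoch %d", epoch)
        bw <- nn_backward(fw, ls$dlogits)
        st <- sgd_step(model, bw$grads, lr, l2, vel)
        model <- st$model; vel <- st$vel
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1
      }
      vf <- nn_forward(model, x_val, train = FALSE)
      vl <- weighted_ce_loss(vf$probs, y_val, weights)$loss
      log[nrow(log) + 1L, ] <- list(epoch, lr, ep_loss / nb, vl)
      if (vl < best$loss - schedule$min_delta) {
        best <- list(loss = vl, layers = model$layers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= schedule$early_stop_patience) break
      }
    }
  })
  model$layers <- best$layers
  structure(list(model = model, config = model$config,
                 latent_width = model$latent_width,
                 best_val_loss = best$loss, best_epoch = best$epoch,
                 class_weights = weights, training_log = log),
            class = "trained_cnn")
}

#' Class probabilities and latent features for preprocessed subjects
#'
#' @param trained a `trained_cnn`
#' @param x subjects x voxels matrix preprocessed identically to training
#' @return list with `probs` (subjects x classes), `latent` (subjects x
#'   latent_width FC2 activations) and `labels` (argmax predictions, 0/1)
#' @export
predict_and_latent <- function(trained, x) {
  if (ncol(x) != prod(trained$model$input_shape))
    stop_input("input shape mismatch: expected %d voxels, got %d",
               prod(trained$model$input_shape), ncol(x))
  fw <- nn_forward(trained$model, x, train = FALSE)
  list(probs = fw$probs, latent = fw$caches$latent,
       labels = max.col(fw$probs) - 1L)
}

#' Nested tuning and refit of the CNN for one outer fold
#'
#' Grid-searches the configuration grid on the inner folds (training on each
#' inner-training set with the held-out inner fold as validation), selects
#' the configuration with the smallest mean inner validation loss, and
#' refits it on the entire outer-training set using a stratified 70/30
#' train/validation split for early stopping.
#'
#' @param x,y full-cohort features and 0/1 labels
#' @param plan a `cv_plan`
#' @param repeat_idx,fold_idx which repeat and outer fold to tune
#' @param grid list of [cnn_config()] objects
#' @param schedule a [training_schedule()]
#' @param seed integer seed
#' @return list with the refit `trained_cnn`, the chosen `config`, and a
#'   `tuning_log` whose `criterion` records the selection rule
#' @export
tune_and_refit <- function(x, y, plan, repeat_idx, fold_idx, grid, schedule,
                           seed = 1L) {
  if (!length(grid)) stop_input("configuration grid is empty")
  rep_plan <- plan$repeats[[repeat_idx]]
  outer_test <- rep_plan$outer[[fold_idx]]
  outer_train <- sort(setdiff(seq_len(length(plan$strata)), outer_test))
  inner <- rep_plan$inner[[fold_idx]]
  mean_losses <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    losses <- numeric(length(inner))
    for (fi in seq_along(inner)) {
      val_idx <- inner[[fi]]
      tr_idx <- sort(setdiff(outer_train, val_idx))
      m <- build_cnn(grid[[gi]], seed = substream_seed(seed, "tune", gi, fi))
      fit <- train_cnn(m, x[tr_idx, , drop = FALSE], y[tr_idx],
                       x[val_idx, , drop = FALSE], y[val_idx], schedule,
                       seed = substream_seed(seed, "tune-train", gi, fi))
      losses[fi] <- fit$best_val_loss
    }
    if (!any(is.finite(losses)))
      stop_input("all candidates diverged; inner losses: %s",
                 paste(signif(losses, 3), collapse = ", "))
    mean_losses[gi] <- mean(losses)
  }
  winner <- which.min(mean_losses)
  sp <- split_train_validation(outer_train, 0.3, plan$strata,
                               seed = substream_seed(seed, "refit-split", repeat_idx, fold_idx))
  m <- build_cnn(grid[[winner]], seed = substream_seed(seed, "refit", repeat_idx, fold_idx))
  fit <- train_cnn(m, x[sp$train, , drop = FALSE], y[sp$train],
                   x[sp$validation, , drop = FALSE], y[sp$validation], schedule,
                   seed = substream_seed(seed, "refit-train", repeat_idx, fold_idx))
  list(trained = fit, config = grid[[winner]],
       tuning_log = data.frame(config = seq_along(grid),
                               mean_inner_loss = mean_losses,
                               criterion = "mean_inner_loss",
                               selected = seq_along(grid) == winner))
}
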
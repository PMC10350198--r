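# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small template anatomy on a 24x28x24 grid
tiny_template <- function() {
  fixture("tiny_template", function() build_anatomy_template(c(24L, 28L, 24L), 2))
}

# small cohort with clear structure (low severity noise)
tiny_cohort <- function() {
  fixture("tiny_cohort", function()
    generate_cohort(cohort_spec(n_subjects = 60L, grid_shape = c(24L, 28L, 24L),
                                noise_sd = 2, n_subtypes = 3L, seed = 11L)))
}

tiny_prep <- function() {
  fixture("tiny_prep", function() preprocess_cohort(tiny_cohort(), 4))
}

# a trained CNN on a separable fixture, shared across saliency/fusion tests
tiny_trained <- function() {
  fixture("tiny_trained", function() {
    co <- tiny_cohort()
    prep <- tiny_prep()
    x <- prep$features
    y <- as.integer(granular_category(co$truth$wab_aq)$severe)
    set.seed(101)
    idx <- sort(sample(nrow(x), 45))
    vidx <- setdiff(seq_len(nrow(x)), idx)
    cfg <- cnn_config(channels = c(8L, 16L), convs_per_block = c(1L, 1L),
                      dropout_rate = 0.6, l2_penalty = 0.001,
                      base_learning_rate = 1e-2,
                      input_shape = prep$dims, allow_small = TRUE)
    fit <- train_cnn(build_cnn(cfg, seed = 7),
                     x[idx, ], y[idx], x[vidx, ], y[vidx],
                     training_schedule(total_epochs = 120L, batch_size = 32L,
                                       early_stop_patience = 120L),
                     seed = 7)
    list(fit = fit, x = x, y = y, train = idx, val = vidx, dims = prep$dims)
  })
}

# brute-force Shapley values by subset enumeration for a value function v
brute_force_shapley <- function(v, M) {
  subsets <- lapply(0:(2^M - 1), function(i) as.logical(bitwAnd(i, 2^(0:(M - 1))) > 0))
  vals <- vapply(subsets, v, numeric(1))
  key <- vapply(subsets, function(z) sum(2^(which(z) - 1)), numeric(1))
  phi <- numeric(M)
  for (j in seq_len(M)) {
    for (si in seq_along(subsets)) {
      z <- subsets[[si]]
      if (z[j]) next
      s <- sum(z)
      w <- factorial(s) * factorial(M - s - 1) / factorial(M)
      z2 <- z; z2[j] <- TRUE
      phi[j] <- phi[j] + w * (vals[key == sum(2^(which(z2) - 1))] - vals[si])
    }
  }
  phi
}
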
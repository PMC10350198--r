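test_that("Grad-CAM++ maps are nonnegative over random inputs", {
  tt <- tiny_trained()
  set.seed(31)
  for (i in 1:100) {
    x <- runif(prod(tt$dims), -1, 1)
    g <- grad_cam_pp(tt$fit, x, class = 1L)
    expect_gte(min(g$values), 0)
  }
})

test_that("a single-channel last conv with uniform gradient gives relu(A)-proportional maps", {
  # one conv block with one channel: cam = w * relu-activation map
  cfg <- cnn_config(channels = c(1L), convs_per_block = c(1L),
                    dropout_rate = 0, input_shape = c(4L, 4L, 4L),
                    allow_small = TRUE)
  # an initialization whose class-score gradient has positive components,
  # so the single channel receives nonzero weight
  m <- build_cnn(cfg, seed = 4)
  trained <- structure(list(model = m, config = cfg, latent_width = m$latent_width),
                       class = "trained_cnn")
  set.seed(104)
  x <- runif(64, -1, 1)
  fw <- lesionsubtype:::nn_forward(m, matrix(x, 1))
  A <- as.numeric(fw$caches$last_conv)
  g <- grad_cam_pp(trained, x, class = 0L)
  expect_gte(min(g$values), 0)
  expect_gt(max(abs(g$values)), 0)
  ratio <- as.numeric(g$values)[A > 0] / A[A > 0]
  expect_lt(diff(range(ratio)) / max(ratio), 1e-6)
})

test_that("a constant head yields a zero Grad-CAM++ map with a warning", {
  tt <- tiny_trained()
  frozen <- tt$fit
  for (i in seq_along(frozen$model$layers)) {
    if (frozen$model$layers[[i]]$type == "dense") {
      frozen$model$layers[[i]]$W[] <- 0
      frozen$model$layers[[i]]$b[] <- 0
    }
  }
  expect_warning(g <- grad_cam_pp(frozen, tt$x[1, ], class = 1L), "zero")
  expect_true(all(g$values == 0))
})

test_that("path attribution is exact for a linear score and complete for the CNN", {
  tt <- tiny_trained()
  # completeness on the real network within 1%
  da <- deep_attribution(tt$fit, tt$x[1, ], 1L,
                         rbind(rep(-1, prod(tt$dims))))
  fx <- lesionsubtype:::cnn_class_score(tt$fit, matrix(tt$x[1, ], 1), 1L)
  fb <- lesionsubtype:::cnn_class_score(tt$fit, matrix(rep(-1, prod(tt$dims)), 1), 1L)
  expect_lte(abs(da$completeness_gap), 0.01 * abs(fx - fb))
  # input equal to its only baseline attributes nothing
  da0 <- deep_attribution(tt$fit, tt$x[2, ], 1L, rbind(tt$x[2, ]))
  expect_equal(max(abs(da0$values)), 0)
  expect_error(deep_attribution(tt$fit, tt$x[1, ], 1L,
                                matrix(0, 0, prod(tt$dims))), "baseline")
})

test_that("kernel SHAP matches brute-force Shapley values on small problems", {
  set.seed(6)
  M <- 8
  w <- rnorm(M)
  f <- function(X) as.numeric(X %*% w)
  bg <- matrix(rnorm(30 * M), 30, M)
  inst <- rnorm(M)
  ks <- kernel_shap(f, inst, bg, n_coalitions = 2^M, knn_fraction = 0.1, seed = 1)
  k <- ceiling(0.1 * 30)
  d2 <- colSums((t(bg) - inst)^2)
  nb <- bg[order(d2)[1:k], , drop = FALSE]
  v <- function(z) {
    syn <- nb
    syn[, z] <- matrix(inst[z], nrow(nb), sum(z), byrow = TRUE)
    mean(f(syn))
  }
  phi_bf <- brute_force_shapley(v, M)
  expect_equal(ks$phi, phi_bf, tolerance = 1e-8)
  # efficiency
  expect_equal(sum(ks$phi), ks$fx - ks$base_value, tolerance = 1e-6)
})

test_that("kernel SHAP respects symmetry and handles constant models", {
  set.seed(7)
  f_sym <- function(X) X[, 1] + X[, 2]
  # background symmetric in the two interchangeable features, so the
  # conditional value function shares the model's symmetry
  half <- matrix(rnorm(20 * 4), 20, 4)
  bg <- rbind(half, half[, c(2, 1, 3, 4)])
  inst <- c(0.5, 0.5, -1, 2)
  ks <- kernel_shap(f_sym, inst, bg, n_coalitions = 2^4, seed = 2)
  expect_equal(ks$phi[1], ks$phi[2], tolerance = 1e-6)
  ks0 <- kernel_shap(function(X) rep(1, nrow(X)), inst, bg, seed = 2)
  expect_true(ks0$constant)
  expect_equal(ks0$phi, rep(0, 4))
  expect_error(kernel_shap(f_sym, inst, bg[1:5, ]), "background")
})

test_that("Monte-Carlo kernel SHAP approximates the exact solution", {
  set.seed(8)
  M <- 10
  w <- rnorm(M)
  f <- function(X) as.numeric(X %*% w) + 0.5 * X[, 1] * X[, 2]
  bg <- matrix(rnorm(50 * M), 50, M)
  inst <- rnorm(M)
  exact <- kernel_shap(f, inst, bg, n_coalitions = 2^M, seed = 3)
  mc <- kernel_shap(f, inst, bg, n_coalitions = 400, seed = 3)
  expect_equal(sum(mc$phi), mc$fx - mc$base_value, tolerance = 1e-6)
  expect_gt(cor(mc$phi, exact$phi), 0.95)
})

test_that("Shapley-flavoured maps agree with each other more than with Grad-CAM++", {
  # the path-gradient CNN attribution and the SVM's kernel-SHAP maps share
  # the baseline-referenced Shapley semantics, while Grad-CAM++ is a
  # channel-weighted activation map; their pairwise eta-squared similarities
  # should reflect that family structure
  tt <- tiny_trained()
  sm <- fit_svm(tt$x[tt$train, ], tt$y[tt$train], svm_config("linear", cost = 1))
  svm_dec <- function(X) predict(sm, X)$decision
  sims <- vapply(tt$val[1:5], function(i) {
    cls <- predict_and_latent(tt$fit, tt$x[i, , drop = FALSE])$labels
    gc <- as.numeric(grad_cam_pp(tt$fit, tt$x[i, ], class = cls)$values)
    da <- as.numeric(deep_attribution(tt$fit, tt$x[i, ], cls,
                                      rbind(rep(-1, prod(tt$dims))),
                                      m_steps = 16L)$values)
    ks <- kernel_shap(svm_dec, tt$x[i, ], tt$x[tt$train, ],
                      n_coalitions = 500, seed = i)$phi
    c(eta_squared_similarity(da, ks),
      eta_squared_similarity(gc, ks),
      eta_squared_similarity(gc, da))
  }, numeric(3))
  expect_gt(mean(sims[1, ]), mean(sims[2, ]))
  expect_gt(mean(sims[1, ]), mean(sims[3, ]))
})

test_that("saliency normalization sums to one and truncates negatives", {
  m <- array(runif(27), c(3, 3, 3))
  nm <- normalize_saliency(m)
  expect_equal(sum(nm), 1, tolerance = 1e-9)
  signed <- m - 0.5
  nm2 <- normalize_saliency(signed, zero_negatives = TRUE)
  expect_equal(sum(nm2), 1, tolerance = 1e-9)
  expect_gte(min(nm2), 0)
  expect_error(normalize_saliency(array(-1, c(2, 2, 2)), zero_negatives = TRUE),
               "zero")
  expect_identical(normalize_saliency(m, zero_negatives = TRUE),
                   normalize_saliency(m, zero_negatives = FALSE))
})

test_that("ROIs partition the left hemisphere and mirror correctly", {
  tm <- tiny_template()
  lesion <- sample_lesion_mask(tm, 0.3, seed = 5)
  rois <- build_rois(lesion, tm$brain, tm$left, ring_width_voxels = 1)
  left_union <- rois$lesion | rois$perilesional | rois$extralesional
  expect_identical(left_union, tm$left & tm$brain)
  expect_false(any(rois$lesion & rois$perilesional))
  expect_false(any(rois$perilesional & rois$extralesional))
  # zero ring width gives an empty perilesional ROI
  r0 <- build_rois(lesion, tm$brain, tm$left, ring_width_voxels = 0)
  expect_equal(sum(r0$perilesional), 0)
  # mirror of mirror returns the original within the brain
  mm <- lesionsubtype:::mirror_x(lesionsubtype:::mirror_x(rois$lesion)) & tm$brain
  expect_identical(mm, rois$lesion & tm$brain)
  expect_error(build_rois(lesionsubtype:::mirror_x(lesion), tm$brain, tm$left),
               "left")
})

test_that("ROI contrasts detect planted class differences and stay calibrated", {
  tm <- tiny_template()
  lesion <- sample_lesion_mask(tm, 0.2, seed = 9)
  rois <- build_rois(lesion, tm$brain, tm$left)
  dm <- dim(tm$brain)
  classes <- rep(c(1, 0), each = 15)
  # planted: severe maps put extra mass in the lesion homologue
  set.seed(40)
  maps <- lapply(seq_along(classes), function(i) {
    m <- array(runif(prod(dm)), dm)
    if (classes[i] == 1) m[rois$lesion_homologue] <- m[rois$lesion_homologue] + 2
    m / sum(m)
  })
  res <- roi_contrast(maps, rois, classes)
  expect_lt(res$p[res$roi == "lesion_homologue"], 0.001)
  # identical class distributions keep the null calibrated
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    nm <- lapply(seq_along(classes), function(i) {
      m <- array(runif(prod(dm)), dm); m / sum(m)
    })
    all(roi_contrast(nm, rois, classes)$p > 0.05, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(ok), 0.7)
  expect_error(roi_contrast(maps, rois, rep(1, 30)), "class")
})
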
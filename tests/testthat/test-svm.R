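toy_2d <- function() {
  x <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1),
             c(-2, -2), c(-2, 2), c(2, -2), c(2, 2))
  y <- as.integer(x[, 1] > 0)
  list(x = x, y = y)
}

test_that("a linearly separable toy problem is fit perfectly", {
  d <- toy_2d()
  m <- fit_svm(d$x, d$y, svm_config("linear", cost = 10))
  pr <- predict(m, d$x)
  expect_identical(pr$labels, d$y)
  expect_lte(m$n_support, nrow(d$x))
  expect_error(fit_svm(cbind(c(1, NA), 0:1), c(0, 1), svm_config("linear")),
               "finite")
})

test_that("inverse-frequency weighting approximates minority duplication", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40, -1.2), 20, 2), matrix(rnorm(10, 1.2), 5, 2))
  y <- c(rep(0, 20), rep(1, 5))
  mw <- fit_svm(x, y, svm_config("linear", cost = 1))
  xd <- rbind(x, do.call(rbind, replicate(3, x[y == 1, ], simplify = FALSE)))
  yd <- c(y, rep(1, 15))
  md <- fit_svm(xd, yd, svm_config("linear", cost = 1),
                weights = c(`0` = 1, `1` = 1))
  grid <- as.matrix(expand.grid(seq(-2, 2, 0.25), seq(-2, 2, 0.25)))
  agree <- mean(predict(mw, grid)$labels == predict(md, grid)$labels)
  expect_gte(agree, 0.9)
})

test_that("the linear kernel ignores the kernel scale", {
  d <- toy_2d()
  p1 <- predict(fit_svm(d$x, d$y, svm_config("linear", cost = 5, kernel_scale = 0.01),
                        seed = 1), d$x)
  p2 <- predict(fit_svm(d$x, d$y, svm_config("linear", cost = 5, kernel_scale = 100),
                        seed = 1), d$x)
  expect_identical(p1$labels, p2$labels)
  expect_equal(p1$decision, p2$decision)
})

test_that("random-search bins are logarithmically spaced", {
  bins <- log_spaced_bins(1e-3, 1e3, 300)
  expect_equal(bins[1], 1e-3)
  expect_equal(bins[300], 1e3)
  ratios <- bins[-1] / bins[-300]
  expect_lt(diff(range(ratios)), 1e-10)
  expect_error(log_spaced_bins(0, 1), "lo")
})

test_that("random search selects by mean inner loss and recovers a planted winner", {
  set.seed(21)
  n <- 60
  x <- matrix(rnorm(n * 5), n, 5)
  y <- as.integer(x[, 1] + 0.2 * rnorm(n) > 0)
  inner <- split(1:n, rep(1:3, length.out = n))
  rs <- random_search_svm(x, y, 1:n, inner, kernel = "linear",
                          n_candidates = 10, seed = 2)
  expect_equal(sum(rs$log$selected), 1)
  expect_equal(rs$log$mean_inner_loss[rs$log$selected],
               min(rs$log$mean_inner_loss))
  expect_s3_class(rs$best_config, "svm_config")
})

test_that("PCA projections are fit on training data only and capture low rank", {
  set.seed(4)
  basis <- matrix(rnorm(30), 3, 10)
  train <- matrix(rnorm(40 * 3), 40, 3) %*% basis
  proj <- fit_projection(train, "pca", 3)
  scores <- project_features(proj, train)
  recon_var <- sum(apply(scores, 2, var))
  total_var <- sum(apply(train, 2, var))
  expect_gte(recon_var / total_var, 0.999)
  # held-out subjects are projected with the identical loadings (no refit)
  test <- matrix(rnorm(10 * 3), 10, 3) %*% basis
  s1 <- project_features(proj, test)
  s2 <- sweep(test, 2, proj$center) %*% proj$loadings
  expect_identical(s1, s2)
  expect_error(fit_projection(train[1:3, ], "pca", 5), "n_components")
})

test_that("ICA keeps the dimensionality of its PCA input and unmixes sources", {
  set.seed(9)
  s1 <- runif(300, -1, 1); s2 <- sign(rnorm(300)) * runif(300)^2
  S <- cbind(s1, s2)
  X <- S %*% matrix(rnorm(2 * 8), 2, 8)
  proj <- fit_projection(X, "ica", 2, seed = 1)
  expect_equal(ncol(proj$loadings), 2)
  Z <- project_features(proj, X)
  # each recovered component matches one true source up to sign
  cors <- abs(cor(Z, S))
  expect_gte(max(cors[1, ]), 0.9)
  expect_gte(max(cors[2, ]), 0.9)
})

test_that("linear-SVM weights map back onto the input grid", {
  prep <- tiny_prep()
  co <- tiny_cohort()
  y <- as.integer(granular_category(co$truth$wab_aq)$severe)
  m <- fit_svm(prep$features, y, svm_config("linear", cost = 1))
  wmap <- svm_weight_map(m, prep$dims)
  expect_equal(dim(wmap), prep$dims)
  expect_error(svm_weight_map(fit_svm(prep$features, y, svm_config("radial")),
                              prep$dims), "linear")
})
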
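#' Configure an SVM baseline
#'
#' @param kernel "linear" or "radial"
#' @param cost soft-margin cost, tuned over [1e-3, 2e4]
#' @param kernel_scale radial kernel scale, tuned over [1e-3, 1e3]
#'   (`gamma = 1 / kernel_scale^2`); ignored for the linear kernel
#' @param reduction "none", "pca" or "ica" front-end projection
#' @param n_components 1-75 retained components when `reduction != "none"`
#' @return object of class `svm_config`
#' @export
svm_config <- function(kernel = c("linear", "radial"), cost = 1,
                       kernel_scale = 1, reduction = c("none", "pca", "ica"),
                       n_components = NULL) {
  kernel <- match.arg(kernel)
  reduction <- match.arg(reduction)
  if (cost <= 0 || kernel_scale <= 0) stop_input("cost and kernel_scale must be positive")
  structure(list(kernel = kernel, cost = cost, kernel_scale = kernel_scale,
                 reduction = reduction, n_components = n_components),
            class = "svm_config")
}

# Platt-style probability calibration: logistic link fit to decision values
# obtained out-of-sample by internal 3-fold CV on the training set.
platt_calibrate <- function(x, y, config, weights, seed) {
  n <- length(y)
  folds <- with_seed(seed, sample(rep_len(1:3, n)))
  dv <- numeric(n)
  for (f in 1:3) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) return(NULL)
    m <- svm_core_fit(x[tr, , drop = FALSE], y[tr], config, weights)
    dv[!tr] <- svm_decision(m, x[!tr, , drop = FALSE])
  }
  suppressWarnings(stats::glm(y ~ dv, family = stats::binomial(),
                              data = data.frame(y = y, dv = dv)))
}

svm_core_fit <- function(x, y, config, weights) {
  args <- list(x = x, y = factor(y, levels = c(0, 1)),
               kernel = config$kernel, cost = config$cost,
               scale = FALSE, class.weights = weights)
  if (config$kernel == "radial") args$gamma <- 1 / config$kernel_scale^2
  do.call(e1071::svm, args)
}

svm_decision <- function(fit, x) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
  # orient decision values so larger means class "1"
  if (colnames(dv)[1] == "0/1") -dv[, 1] else dv[, 1]
}

#' Fit a class-weighted SVM with calibrated probability outputs
#'
#' Wraps the SMO solver in `e1071::svm` (hinge loss, per-class cost
#' weighting) and adds a Platt-style logistic calibration of the decision
#' values fit on internal out-of-sample predictions, since the fusion stage
#' consumes class probabilities.
#'
#' @param x features (subjects x features), finite
#' @param y 0/1 labels (both classes present)
#' @param config an [svm_config()]
#' @param weights named per-class weights (default inverse class frequencies)
#' @param seed seed for the internal calibration folds
#' @return object of class `trained_svm`
#' @export
fit_svm <- function(x, y, config, weights = NULL, seed = 1L) {
  if (!all(is.finite(x))) stop_input("features must be finite")
  if (length(unique(y)) < 2) stop_input("need both classes to fit an SVM")
  if (is.null(weights)) {
    w <- class_weights(y)
  } else w <- weights
  wn <- stats::setNames(as.numeric(w), c("0", "1"))
  fit <- svm_core_fit(x, y, config, wn)
  cal <- platt_calibrate(x, y, config, wn, substream_seed(seed, "platt"))
  structure(list(fit = fit, calibration = cal, config = config,
                 n_support = nrow(fit$SV)),
            class = "trained_svm")
}

#' Predict class probabilities from a trained SVM
#' @param object a `trained_svm`
#' @param newdata feature matrix
#' @param ... unused
#' @return list with `probs` (subjects x 2), `decision` values and `labels`
#' @export
predict.trained_svm <- function(object, newdata, ...) {
  dv <- svm_decision(object$fit, newdata)
  p1 <- if (is.null(object$calibration)) stats::plogis(dv) else
    stats::predict(object$calibration, data.frame(dv = dv), type = "response")
  probs <- cbind(`0` = 1 - p1, `1` = p1)
  # class labels follow the SVM decision rule itself; the calibrated
  # probabilities exist for fusion (averaging/stacking) only
  list(probs = probs, decision = dv, labels = as.integer(dv > 0))
}

#' Log-spaced candidate bins for random search
#' @param lo,hi positive range endpoints
#' @param n_bins number of bins (default 300)
#' @return numeric vector of `n_bins` logarithmically spaced values
#' @export
log_spaced_bins <- function(lo, hi, n_bins = 300L) {
  if (lo <= 0 || hi <= lo) stop_input("need 0 < lo < hi")
  exp(seq(log(lo), log(hi), length.out = n_bins))
}

#' Random-search tuning of an SVM on the inner folds
#'
#' Draws candidate values from 300 logarithmically spaced bins per parameter
#' (without replacement, one value per bin) and selects the candidate with
#' the smallest mean inner-fold class-weighted log loss. The kernel is not
#' tuned: separate models are fit per kernel.
#'
#' @param x,y full-cohort features and labels
#' @param outer_train_indices outer-training subject indices
#' @param inner_folds list of inner-fold index vectors partitioning the
#'   outer-training set
#' @param kernel "linear" or "radial"
#' @param reduction "none", "pca" or "ica"
#' @param cost_range,scale_range tuning ranges
#' @param n_bins bins per parameter (default 300)
#' @param n_candidates tuning budget (default 60)
#' @param max_components upper bound for the component-count parameter
#' @param seed integer seed
#' @return list with `best_config` and the full `log` of candidates
#' @export
random_search_svm <- function(x, y, outer_train_indices, inner_folds,
                              kernel = "linear", reduction = "none",
                              cost_range = c(1e-3, 2e4),
                              scale_range = c(1e-3, 1e3),
                              n_bins = 300L, n_candidates = 60L,
                              max_components = 75L, seed = 1L) {
  cost_bins <- log_spaced_bins(cost_range[1], cost_range[2], n_bins)
  scale_bins <- log_spaced_bins(scale_range[1], scale_range[2], n_bins)
  n_candidates <- min(n_candidates, n_bins)
  cand <- with_seed(substream_seed(seed, "draw"), {
    comp_max <- min(max_components, length(outer_train_indices) -
                      max(lengths(inner_folds)) - 1L, ncol(x))
    data.frame(cost = cost_bins[sample.int(n_bins, n_candidates)],
               kernel_scale = scale_bins[sample.int(n_bins, n_candidates)],
               n_components = if (reduction == "none") NA_integer_ else
                 sample.int(max(1L, comp_max), n_candidates, replace = TRUE))
  })
  if (!nrow(cand)) stop_input("empty candidate set")
  losses <- numeric(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    cfg <- svm_config(kernel, cand$cost[ci], cand$kernel_scale[ci], reduction,
                      if (reduction == "none") NULL else cand$n_components[ci])
    fl <- numeric(length(inner_folds))
    for (fi in seq_along(inner_folds)) {
      val <- inner_folds[[fi]]
      tr <- sort(setdiff(outer_train_indices, val))
      fl[fi] <- tryCatch({
        proj <- if (reduction == "none") NULL else
          fit_projection(x[tr, , drop = FALSE], reduction, cfg$n_components,
                         seed = substream_seed(seed, "proj", ci, fi))
        xtr <- if (is.null(proj)) x[tr, , drop = FALSE] else
          project_features(proj, x[tr, , drop = FALSE])
        xva <- if (is.null(proj)) x[val, , drop = FALSE] else
          project_features(proj, x[val, , drop = FALSE])
        m <- fit_svm(xtr, y[tr], cfg, seed = substream_seed(seed, "fit", ci, fi))
        pr <- predict(m, xva)$probs[, 2]
        w <- class_weights(y[tr])[as.character(y[val])]
        -mean(w * (y[val] * log(pmax(pr, 1e-12)) +
                     (1 - y[val]) * log(pmax(1 - pr, 1e-12))))
      }, error = function(e) Inf)
    }
    losses[ci] <- mean(fl)
  }
  best <- which.min(losses)
  best_config <- svm_config(kernel, cand$cost[best], cand$kernel_scale[best],
                            reduction,
                            if (reduction == "none") NULL else cand$n_components[best])
  list(best_config = best_config,
       log = cbind(cand, mean_inner_loss = losses,
                   selected = seq_len(nrow(cand)) == best))
}

# symmetric FastICA (logcosh contrast) on whitened data; returns the
# unmixing applied to the input columns
fastica_symmetric <- function(Z, seed, max_iter = 200L, tol = 1e-6) {
  k <- ncol(Z)
  n <- nrow(Z)
  W <- with_seed(seed, matrix(stats::rnorm(k * k), k, k))
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)           # n x k component estimates
    g <- tanh(WX)
    gp <- 1 - g^2
    W_new <- crossprod(g, Z) / n - diag(colMeans(gp), k) %*% W
    W_new <- sym_decor(W_new)
    if (max(abs(abs(diag(W_new %*% t(W))) - 1)) < tol) { W <- W_new; break }
    W <- W_new
  }
  W
}

#' Fit a PCA or ICA projection on training features only
#'
#' PCA is fit by singular value decomposition of the centered training
#' matrix. ICA is applied to the retained PCA component scores (whitened),
#' relaxing the orthogonality constraint while keeping the dimensionality of
#' its PCA input. The returned projector applies fixed loadings to held-out
#' subjects without refitting.
#'
#' @param x training features (subjects x features)
#' @param method "pca" or "ica"
#' @param n_components number of retained components,
#'   `<= min(n_train - 1, n_features)`
#' @param seed seed for the ICA initialization
#' @return object of class `projection` with fields `center` and `loadings`
#' @export
fit_projection <- function(x, method = c("pca", "ica"), n_components, seed = 1L) {
  method <- match.arg(method)
  if (n_components > min(nrow(x) - 1L, ncol(x)))
    stop_input("n_components (%d) exceeds min(n_train - 1, n_features)", n_components)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = n_components)
  loadings <- sv$v                               # features x k
  if (method == "ica") {
    scores <- xc %*% loadings                    # n x k PCA scores
    sdv <- sqrt(colMeans(scores^2)) + 1e-12
    Z <- sweep(scores, 2, sdv, `/`)              # whitened-ish scores
    W <- fastica_symmetric(Z, substream_seed(seed, "ica"))
    loadings <- sweep(loadings, 2, sdv, `/`) %*% t(W)
  }
  structure(list(center = ctr, loadings = loadings, method = method,
                 n_components = n_components),
            class = "projection")
}

#' Apply a fitted projection to new subjects
#' @param proj a `projection`
#' @param x feature matrix on the same grid as the training features
#' @return subjects x n_components score matrix
#' @export
project_features <- function(proj, x) {
  sweep(x, 2, proj$center) %*% proj$loadings
}

#' Map linear-SVM weights back onto the voxel grid
#' @param trained a `trained_svm` with linear kernel fit on flattened maps
#' @param dims 3D grid dimensions of the input maps
#' @return 3D array of primal weights
#' @export
svm_weight_map <- function(trained, dims) {
  if (trained$config$kernel != "linear")
    stop_input("weight maps are defined for the linear kernel only")
  w <- crossprod(trained$fit$SV, trained$fit$coefs)
  if (length(w) != prod(dims)) stop_input("weight length does not match grid")
  array(as.numeric(w), dims)
}
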
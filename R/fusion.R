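#' Weighted-average ensemble of CNN and SVM probabilities
#'
#' Computes `p = w * p_cnn + (1 - w) * p_svm` over a grid of weights
#' (w = 1 reproduces the CNN, w = 0 the SVM), predicts by argmax, and
#' returns the F1 curve over the grid.
#'
#' @param p_cnn,p_svm subjects x 2 probability matrices with matching
#'   rownames identifying subjects
#' @param y_true 0/1 labels aligned with the rows
#' @param weight_grid weights in [0, 1] (default 101 points, step 0.01)
#' @return list with `curve` (data frame weight, f1) and `predictions`
#'   (list of 0/1 vectors per weight)
#' @export
weighted_average_ensemble <- function(p_cnn, p_svm, y_true,
                                      weight_grid = seq(0, 1, by = 0.01)) {
  if (!is.null(rownames(p_cnn)) && !is.null(rownames(p_svm)) &&
      !identical(rownames(p_cnn), rownames(p_svm)))
    stop_input("probability matrices are not aligned by subject")
  if (nrow(p_cnn) != nrow(p_svm)) stop_input("probability matrices differ in size")
  preds <- lapply(weight_grid, function(w) {
    p <- w * p_cnn + (1 - w) * p_svm
    max.col(p) - 1L
  })
  f1 <- vapply(preds, function(pr) confusion_metrics(y_true, pr)$f1, numeric(1))
  list(curve = data.frame(weight = weight_grid, f1 = f1), predictions = preds)
}

# ridge LDA fallback used when the pooled within-class covariance is singular
ridge_lda <- function(X, y, ridge = 1e-6) {
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  R <- X
  R[y == 0, ] <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
  R[y == 1, ] <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
  S <- crossprod(R) / max(1, nrow(X) - 2)
  S <- S + diag(ridge * (1 + diag(S)), ncol(X))
  w <- solve(S, mu1 - mu0)
  b <- -sum(w * (mu0 + mu1) / 2) + log(mean(y == 1) / mean(y == 0))
  list(w = w, b = b)
}

#' Stack CNN and SVM predictions with a linear discriminant meta-learner
#'
#' Fits an LDA decision rule over the 2D space of severe-class
#' probabilities, using only training-fold predictions (an audit log of the
#' fit indices is retained). A singular within-class covariance triggers a
#' ridge-regularized fallback with a warning.
#'
#' @param p_cnn,p_svm severe-class probabilities of the two base models on
#'   the meta-training subjects
#' @param labels 0/1 labels of those subjects
#' @param train_ids optional identifiers recorded in the audit log
#' @return object of class `meta_learner`
#' @export
stack_meta_learner <- function(p_cnn, p_svm, labels, train_ids = NULL) {
  X <- cbind(cnn = p_cnn, svm = p_svm)
  fit <- tryCatch(MASS::lda(X, grouping = factor(labels, levels = c(0, 1))),
                  error = function(e) NULL)
  if (is.null(fit) || inherits(tryCatch(stats::predict(fit, X),
                                        error = function(e) e), "error")) {
    warning("singular covariance in LDA stacking; using ridge fallback")
    fit <- ridge_lda(X, labels)
    class(fit) <- "ridge_lda"
  }
  structure(list(fit = fit, audit = list(train_ids = train_ids %||% seq_along(labels))),
            class = "meta_learner")
}

#' Apply a stacked meta-learner to held-out probabilities
#' @param object a `meta_learner`
#' @param p_cnn,p_svm severe-class probabilities on held-out subjects
#' @param ... unused
#' @return 0/1 predicted labels
#' @export
predict.meta_learner <- function(object, p_cnn, p_svm, ...) {
  X <- cbind(cnn = p_cnn, svm = p_svm)
  if (inherits(object$fit, "ridge_lda")) {
    as.integer(X %*% object$fit$w + object$fit$b > 0)
  } else {
    as.integer(as.character(stats::predict(object$fit, X)$class))
  }
}

#' Cross-validated linear SVM on CNN-derived features
#'
#' Trains and tunes a linear SVM on latent features or per-subject saliency
#' maps under the shared CV plan. Feature maps for each subject must come
#' from the fold model under which that subject was in the test set, so the
#' features themselves carry no leakage; the SVM is then trained on
#' outer-training subjects and evaluated on pooled outer-test predictions.
#'
#' @param features subjects x features matrix (latent width or voxel count)
#' @param labels 0/1 labels
#' @param plan a `cv_plan`
#' @param repeats which repeats to run (default all)
#' @param n_candidates tuning budget per fold
#' @param seed integer seed
#' @return list with per-repeat `records` (performance data frame) and the
#'   pooled `predictions`
#' @export
downstream_svm <- function(features, labels, plan, repeats = seq_len(plan$n_repeats),
                           n_candidates = 12L, seed = 1L) {
  if (any(!is.finite(features))) stop_input("missing saliency/features for some subject")
  preds <- list()
  for (r in repeats) {
    y_pred <- integer(length(labels))
    for (f in seq_len(plan$n_outer)) {
      test <- plan$repeats[[r]]$outer[[f]]
      train <- sort(setdiff(seq_along(labels), test))
      rs <- random_search_svm(features, labels, train,
                              plan$repeats[[r]]$inner[[f]],
                              kernel = "linear", n_candidates = n_candidates,
                              seed = substream_seed(seed, r, f))
      m <- fit_svm(features[train, , drop = FALSE], labels[train],
                   rs$best_config, seed = substream_seed(seed, "fit", r, f))
      y_pred[test] <- predict(m, features[test, , drop = FALSE])$labels
    }
    preds[[length(preds) + 1L]] <- list(y_true = labels, y_pred = y_pred)
  }
  list(records = evaluate_repeats(preds), predictions = preds)
}
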
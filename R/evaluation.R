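#' Confusion-table metrics for severe-aphasia prediction
#'
#' Computes the performance record from the pooled confusion table, with
#' the severe class as positive. Recall equals the severe-class accuracy,
#' balanced accuracy is the mean of the two class accuracies, and F1 is the
#' harmonic mean of precision and recall (0 when both are 0). Divisions by
#' zero yield 0 and set `division_flag`.
#'
#' @param y_true,y_pred aligned 0/1 label vectors (1 = severe)
#' @param repeat_index optional bookkeeping index
#' @return one-row data frame with `acc_severe`, `acc_nonsevere`,
#'   `balanced_accuracy`, `precision`, `recall`, `f1`, `division_flag`
#' @export
confusion_metrics <- function(y_true, y_pred, repeat_index = NA_integer_) {
  if (length(y_true) != length(y_pred))
    stop_input("label vectors are not aligned (lengths %d vs %d)",
               length(y_true), length(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  flag <- FALSE
  safe_div <- function(a, b) {
    if (b == 0) { flag <<- TRUE; 0 } else a / b
  }
  recall <- safe_div(tp, tp + fn)        # = severe-class accuracy
  acc_nonsevere <- safe_div(tn, tn + fp)
  precision <- safe_div(tp, tp + fp)
  f1 <- if (precision + recall == 0) { flag <- TRUE; 0 } else
    2 * precision * recall / (precision + recall)
  data.frame(acc_severe = recall, acc_nonsevere = acc_nonsevere,
             balanced_accuracy = mean(c(recall, acc_nonsevere)),
             precision = precision, recall = recall, f1 = f1,
             division_flag = flag, repeat_index = repeat_index)
}

#' Label-permutation test of a prediction pipeline
#'
#' Reruns the full model building and testing procedure on randomly permuted
#' class labels and compares the observed F1 score against the null
#' distribution using the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_permutations)`.
#'
#' @param runner function(labels, seed) returning an F1 score; must be
#'   deterministic given its arguments
#' @param labels the true 0/1 labels
#' @param n_permutations number of label permutations (default 500)
#' @param seed integer seed
#' @return list with `observed`, `null` (vector of permuted F1 scores) and `p`
#' @export
permutation_test <- function(runner, labels, n_permutations = 500L, seed = 1L) {
  if (n_permutations < 1) stop_input("n_permutations must be >= 1")
  observed <- runner(labels, substream_seed(seed, "obs"))
  null <- with_seed(substream_seed(seed, "perm"), {
    vapply(seq_len(n_permutations), function(i)
      runner(sample(labels), substream_seed(seed, "perm", i)), numeric(1))
  })
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_permutations))
}

#' Paired comparison of two models across CV repeats
#'
#' Two-sided paired t-test with `df = n - 1` plus Cohen's d on the paired
#' differences (`mean(diff) / sd(diff)`).
#'
#' @param scores_a,scores_b per-repeat scores of the two models, same repeats
#' @return list with `t`, `df`, `p`, `d`, `mean_diff`
#' @export
paired_compare <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2)
    stop_input("scores must have equal length >= 2")
  diffs <- scores_a - scores_b
  if (stats::sd(diffs) == 0)
    stop_input("zero-variance differences: paired t-test degenerate")
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(diffs) / stats::sd(diffs),
       mean_diff = mean(diffs))
}

#' Per-repeat pooled evaluation of cross-validated predictions
#'
#' Concatenates outer-fold test predictions within each repeat and scores
#' the pooled vector once (pooled-then-scored).
#'
#' @param predictions list over repeats; each element holds `y_true` and
#'   `y_pred` pooled across outer folds
#' @return data frame of per-repeat performance records
#' @export
evaluate_repeats <- function(predictions) {
  do.call(rbind, lapply(seq_along(predictions), function(r)
    confusion_metrics(predictions[[r]]$y_true, predictions[[r]]$y_pred,
                      repeat_index = r)))
}
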
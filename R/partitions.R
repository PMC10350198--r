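#' WAB-R severity category and binary severe label
#'
#' Maps a WAB-AQ score to the granular WAB-R category used for
#' stratification -- very severe (0-25), severe (26-50), moderate (51-75),
#' mild (76 and above; non-integer scores between 75 and 76 are treated as
#' moderate) -- and to the binary label: severe iff WAB-AQ <= 50.
#'
#' @param wab_aq numeric vector of scores in [0, 100]
#' @return data frame with ordered factor `category` and logical `severe`
#' @export
granular_category <- function(wab_aq) {
  if (any(wab_aq < 0 | wab_aq > 100)) stop_input("wab_aq must be within [0, 100]")
  category <- ifelse(wab_aq <= 25, "very_severe",
              ifelse(wab_aq <= 50, "severe",
              ifelse(wab_aq < 76, "moderate", "mild")))
  data.frame(category = factor(category,
                               levels = c("very_severe", "severe", "moderate", "mild"),
                               ordered = TRUE),
             severe = wab_aq <= 50)
}

# Merge strata too small to appear in every fold into the adjacent severity
# category (next level up; the last level merges downward).
merge_small_strata <- function(strata, min_size) {
  strata <- factor(strata, levels = levels(strata)[table(strata)[levels(strata)] > 0 |
                                                     TRUE])
  repeat {
    tab <- table(strata)
    small <- names(tab)[tab > 0 & tab < min_size]
    if (!length(small)) break
    lv <- levels(strata)
    s <- small[1]
    pos <- match(s, lv)
    nonempty <- which(table(strata)[lv] > 0 & lv != s)
    if (!length(nonempty)) break
    target <- lv[nonempty[which.min(abs(nonempty - pos))]]
    strata[strata == s] <- target
    strata <- droplevels(strata)
  }
  droplevels(strata)
}

# Deal indices round-robin into n_folds, shuffling within stratum and
# continuing a global rotation pointer across strata so overall fold sizes
# differ by at most one while per-fold stratum counts stay within +/- 1.
deal_stratified <- function(indices, strata, n_folds, seed) {
  folds <- vector("list", n_folds)
  ptr <- 0L
  with_seed(seed, {
    for (s in levels(strata)) {
      members <- indices[strata == s]
      if (!length(members)) next
      members <- members[sample.int(length(members))]
      for (m in members) {
        f <- (ptr %% n_folds) + 1L
        folds[[f]] <- c(folds[[f]], m)
        ptr <- ptr + 1L
      }
    }
  })
  lapply(folds, sort)
}

#' Build a repeated nested stratified cross-validation plan
#'
#' Preallocates every partition used by every model so that CNN, SVM and
#' fusion variants consume byte-identical folds and paired comparisons across
#' repeats are equitable. Outer test folds partition the cohort; inner folds
#' partition each outer-training set. Stratification uses the granular WAB-R
#' categories; strata smaller than the fold count are merged with the
#' adjacent severity category.
#'
#' @param strata factor of per-subject granular categories
#' @param n_repeats number of cross-validation repeats (default 20)
#' @param n_outer outer folds (default 6)
#' @param n_inner inner folds per outer-training set (default 8)
#' @param seed integer seed; plans are deterministic given it
#' @return object of class `cv_plan`
#' @export
build_cv_plan <- function(strata, n_repeats = 20L, n_outer = 6L, n_inner = 8L,
                          seed = 1L) {
  n <- length(strata)
  if (n_outer > n) stop_input("n_outer exceeds cohort size")
  strata <- merge_small_strata(factor(strata), max(n_outer, n_inner))
  repeats <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    outer <- deal_stratified(seq_len(n), strata, n_outer,
                             substream_seed(seed, "outer", r))
    inner <- vector("list", n_outer)
    for (f in seq_len(n_outer)) {
      tr <- sort(setdiff(seq_len(n), outer[[f]]))
      inner[[f]] <- deal_stratified(tr, droplevels(strata[tr]), n_inner,
                                    substream_seed(seed, "inner", r, f))
    }
    repeats[[r]] <- list(outer = outer, inner = inner)
  }
  structure(list(n_repeats = as.integer(n_repeats), n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner), strata = strata,
                 seed = as.integer(seed), repeats = repeats),
            class = "cv_plan")
}

#' Stratified train/validation split of an outer-training set
#'
#' @param outer_train_indices integer indices of the outer-training subjects
#' @param validation_fraction fraction held out for validation (default 0.3)
#' @param strata factor over the full cohort
#' @param seed integer seed
#' @return list with integer vectors `train` and `validation`
#' @export
split_train_validation <- function(outer_train_indices, validation_fraction = 0.3,
                                   strata, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop_input("validation_fraction must be inside (0, 1)")
  n <- length(outer_train_indices)
  n_val <- max(1L, as.integer(round(validation_fraction * n)))
  st <- droplevels(factor(strata[outer_train_indices]))
  # largest-remainder apportionment of the validation quota across strata
  tab <- table(st)
  quota <- n_val * as.numeric(tab) / n
  base <- floor(quota)
  rem <- n_val - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  val <- integer(0)
  with_seed(seed, {
    for (i in seq_along(tab)) {
      members <- outer_train_indices[st == names(tab)[i]]
      take <- min(base[i], length(members) - 1L)  # never empty a stratum from train
      if (take > 0) val <- c(val, sample(members, take))
    }
  })
  if (length(val) < n_val)
    warning("stratum too small to honour the split exactly; validation slightly smaller")
  list(train = sort(setdiff(outer_train_indices, val)), validation = sort(val))
}

#' Serialize a CV plan to JSON
#' @param plan a `cv_plan`
#' @param path output path
#' @export
write_cv_plan <- function(plan, path) {
  obj <- list(n_repeats = plan$n_repeats, n_outer = plan$n_outer,
              n_inner = plan$n_inner, seed = plan$seed,
              strata = as.character(plan$strata),
              strata_levels = levels(plan$strata),
              repeats = plan$repeats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a CV plan written by [write_cv_plan()] bit-exactly
#' @param path JSON path
#' @return a `cv_plan`
#' @export
read_cv_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  to_idx <- function(x) lapply(x, function(v) as.integer(unlist(v)))
  repeats <- lapply(obj$repeats, function(r)
    list(outer = to_idx(r$outer), inner = lapply(r$inner, to_idx)))
  obj$strata <- unlist(obj$strata)
  obj$strata_levels <- unlist(obj$strata_levels)
  structure(list(n_repeats = as.integer(obj$n_repeats),
                 n_outer = as.integer(obj$n_outer),
                 n_inner = as.integer(obj$n_inner),
                 strata = factor(obj$strata, levels = obj$strata_levels, ordered = TRUE),
                 seed = as.integer(obj$seed), repeats = repeats),
            class = "cv_plan")
}
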
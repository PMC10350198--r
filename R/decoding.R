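# Chi-square meta-analytic topic maps from a synthetic study corpus and
# correlation-based decoding of exemplar saliency maps. The corpus stands in
# for a large author-topic model of the neuroimaging literature: studies
# report binary voxel activations, topics tag subsets of studies, and a
# topic's meta-map contrasts activation rates between tagged and untagged
# studies voxel by voxel.

#' Simulate a topic-tagged study corpus
#'
#' Studies activate brain voxels at a baseline rate; for topics with a
#' planted spatial pattern, member studies activate voxels inside the
#' pattern with odds inflated by `odds_ratio`, creating a recoverable
#' topic-region association.
#'
#' @param brain_mask logical 3D array of analyzable voxels
#' @param n_studies number of studies (default 400)
#' @param n_topics number of topics (default 200)
#' @param base_rate baseline voxel activation probability (default 0.05)
#' @param membership_rate probability a study is tagged with a topic
#' @param planted named list mapping topic index (as character) to a 3D
#'   pattern array in [0, 1]; activation odds inside the pattern are
#'   multiplied by `odds_ratio` for member studies
#' @param odds_ratio activation odds multiplier for planted topics (default 8)
#' @param seed integer seed
#' @return object of class `topic_corpus` with `activation` (studies x
#'   brain voxels), `topic_membership` (studies x topics), `voxel_index`,
#'   `dims`
#' @export
simulate_topic_corpus <- function(brain_mask, n_studies = 400L, n_topics = 200L,
                                  base_rate = 0.05, membership_rate = 0.1,
                                  planted = list(), odds_ratio = 8,
                                  seed = 1L) {
  vox <- which(brain_mask)
  V <- length(vox)
  with_seed(substream_seed(seed, "corpus"), {
    membership <- matrix(stats::runif(n_studies * n_topics) < membership_rate,
                         n_studies, n_topics)
    # every topic needs at least one member and one non-member study
    for (t in seq_len(n_topics)) {
      if (!any(membership[, t])) membership[sample.int(n_studies, 1), t] <- TRUE
      if (all(membership[, t])) membership[sample.int(n_studies, 1), t] <- FALSE
    }
    base_odds <- base_rate / (1 - base_rate)
    activation <- matrix(stats::runif(n_studies * V) < base_rate, n_studies, V)
    for (tname in names(planted)) {
      t <- as.integer(tname)
      pat <- planted[[tname]][vox]
      odds <- base_odds * (1 + (odds_ratio - 1) * pat)
      p <- odds / (1 + odds)
      members <- which(membership[, t])
      for (s in members)
        activation[s, ] <- stats::runif(V) < p
    }
    structure(list(activation = activation, topic_membership = membership,
                   voxel_index = vox, dims = dim(brain_mask)),
              class = "topic_corpus")
  })
}

#' Chi-square meta-analytic map for one topic
#'
#' At each voxel, forms the 2x2 contingency table of activation
#' (active/inactive) by topic membership (member/non-member) and computes
#' the chi-square statistic without continuity correction. The map value is
#' `sign(observed - expected for active-and-member) * sqrt(chi2)`; voxels
#' with a zero margin score 0.
#'
#' @param corpus a `topic_corpus`
#' @param topic topic index
#' @return object of class `topic_meta_map` with `values` (3D array) and
#'   `topic_id`
#' @export
chi_square_meta_map <- function(corpus, topic) {
  member <- corpus$topic_membership[, topic]
  if (!any(member) || all(member))
    stop_input("topic %d lacks member or non-member studies", topic)
  n1 <- sum(member); n0 <- sum(!member); n <- n1 + n0
  act <- corpus$activation
  a <- colSums(act[member, , drop = FALSE])     # active & member
  c_ <- colSums(act[!member, , drop = FALSE])   # active & non-member
  b <- n1 - a                                   # inactive & member
  d <- n0 - c_
  row1 <- a + c_; row0 <- b + d
  denom <- as.numeric(row1) * row0 * n1 * n0
  chi2 <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  val <- sign(a - n1 * row1 / n) * sqrt(chi2)
  vol <- array(0, corpus$dims)
  vol[corpus$voxel_index] <- val
  structure(list(values = vol, topic_id = topic), class = "topic_meta_map")
}

#' Decode an exemplar saliency map against topic meta-maps
#'
#' Correlates the saliency map with every topic meta-map over non-lesion
#' brain voxels (Pearson), Bonferroni-corrects the p-values by the number of
#' topics (capped at 1), and retains topics with `r > r_threshold` and
#' corrected `p < corrected_p_threshold`, ranked by correlation.
#'
#' @param exemplar_map 3D saliency array (or `saliency_map`)
#' @param lesion_mask logical array of voxels to exclude
#' @param topic_maps list of `topic_meta_map`s (or 3D arrays)
#' @param brain_mask logical array restricting the correlation domain
#' @param r_threshold minimum retained correlation (default 0.2)
#' @param corrected_p_threshold maximum corrected p (default 1e-4)
#' @return data frame of all topics (`topic`, `r`, `p_corrected`,
#'   `retained`), ranked by `r` descending
#' @export
decode_saliency <- function(exemplar_map, lesion_mask, topic_maps, brain_mask,
                            r_threshold = 0.2, corrected_p_threshold = 1e-4) {
  sal <- if (inherits(exemplar_map, "saliency_map")) exemplar_map$values else exemplar_map
  keep <- brain_mask & !lesion_mask
  if (sum(keep) < 10) stop_input("fewer than 10 voxels remain after lesion removal")
  sv <- sal[keep]
  if (stats::sd(sv) == 0) stop_input("saliency constant over masked voxels: correlation undefined")
  n_topics <- length(topic_maps)
  nv <- sum(keep)
  res <- do.call(rbind, lapply(seq_len(n_topics), function(i) {
    tm <- topic_maps[[i]]
    tv <- (if (inherits(tm, "topic_meta_map")) tm$values else tm)[keep]
    if (stats::sd(tv) == 0) return(data.frame(topic = i, r = 0, p_corrected = 1))
    r <- stats::cor(sv, tv)
    tstat <- r * sqrt((nv - 2) / max(1 - r^2, 1e-15))
    p <- 2 * stats::pt(-abs(tstat), df = nv - 2)
    data.frame(topic = i, r = r, p_corrected = min(1, p * n_topics))
  }))
  res$retained <- res$r > r_threshold & res$p_corrected < corrected_p_threshold
  res[order(-res$r), ]
}
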
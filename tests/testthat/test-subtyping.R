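blob_maps <- function(n_per, centers, V = 60, noise = 0.05, seed = 1) {
  # groups of 1D "maps" with group-specific bumps
  set.seed(seed)
  do.call(rbind, lapply(seq_along(centers), function(g) {
    t(vapply(seq_len(n_per), function(i) {
      m <- numeric(V)
      m[centers[[g]]] <- 1
      m + rnorm(V, 0, noise)
    }, numeric(V)))
  }))
}

test_that("eta-squared similarity matches its hand-computed values", {
  a <- runif(50)
  expect_equal(eta_squared_similarity(a, a), 1)
  expect_equal(eta_squared_similarity(c(0, 1), c(1, 0)), 0)
  # offsets reduce similarity below 1, unlike Pearson correlation
  b <- a + 0.5
  expect_lt(eta_squared_similarity(a, b), 1)
  expect_equal(cor(a, b), 1)
  expect_error(eta_squared_similarity(rep(1, 5), rep(1, 5)), "constant")
  expect_error(eta_squared_similarity(1:3, 1:4), "equal length")
})

test_that("eta-distance k-means recovers identical-map groups exactly", {
  maps <- rbind(matrix(rep(c(1, 0, 1, 0, 0, 1), 4), 4, 6, byrow = TRUE),
                matrix(rep(c(0, 1, 0, 1, 1, 0), 4), 4, 6, byrow = TRUE))
  km <- kmeans_eta(maps, 2, n_replicates = 5, seed = 1)
  expect_equal(length(unique(km$assignments[1:4])), 1)
  expect_equal(length(unique(km$assignments[5:8])), 1)
  expect_false(km$assignments[1] == km$assignments[5])
  expect_equal(km$total_distance, 0, tolerance = 1e-12)
  km1 <- kmeans_eta(maps, 1, n_replicates = 2, seed = 1)
  expect_equal(unique(km1$assignments), 1L)
  expect_equal(min(km$replicate_distances), km$total_distance)
  expect_error(kmeans_eta(maps, 0), "k")
  expect_error(kmeans_eta(maps, 9), "exceeds")
})

test_that("consensus matrices are symmetric block structures on separable groups", {
  maps <- blob_maps(6, list(1:10, 31:40), noise = 0.05, seed = 3)
  cm <- consensus_matrix(maps, 2, n_runs = 50, n_replicates = 5, seed = 2)
  C <- cm$values
  expect_identical(C, t(C))
  expect_true(all(diag(C) == 1))
  expect_true(all(C >= 0 & C <= 1))
  within <- c(C[1:6, 1:6][upper.tri(C[1:6, 1:6])],
              C[7:12, 7:12][upper.tri(C[7:12, 7:12])])
  between <- C[1:6, 7:12]
  expect_gte(min(within), 0.95)
  expect_lte(max(between), 0.05)
  # duplicated maps always co-cluster
  maps2 <- rbind(maps, maps[1, ])
  cm2 <- consensus_matrix(maps2, 2, n_runs = 20, n_replicates = 3, seed = 2)
  expect_equal(cm2$values[1, 13], 1)
})

test_that("the dip statistic and test behave as on reference distributions", {
  expect_equal(dip_stat(c(rep(0, 100), rep(1, 100))), 0.25)
  expect_equal(dip_stat(1:100), 1 / 200)
  expect_gte(dip_stat(rnorm(50)), 0)
  bim <- dip_test(c(rep(0, 100), rep(1, 100)), n_boot = 300, seed = 1)
  expect_lt(bim$p, 0.01)
  uni <- vapply(1:20, function(s) {
    set.seed(s)
    dip_test(rnorm(200), n_boot = 200, seed = s)$p > 0.05
  }, logical(1))
  expect_gte(mean(uni), 0.9)
  expect_equal(dip_test(rep(2, 10))$p, 1)
  expect_error(dip_test(1:3), "4")
})

test_that("PAC counts strictly ambiguous consensus entries", {
  # six entries, exactly one strictly inside (0.1, 0.9)
  M <- diag(4)
  M[upper.tri(M)] <- c(0.05, 0.5, 0.95, 0.95, 0.08, 0.91)
  M <- M + t(M) - diag(diag(M)); diag(M) <- 1
  expect_equal(pac_score(M), 1 / 6)
  all01 <- matrix(sample(c(0, 1), 25, TRUE), 5); all01 <- (all01 + t(all01)) / 2
  all01[all01 == 0.5] <- 1; diag(all01) <- 1
  expect_equal(pac_score(all01), 0)
  half <- matrix(0.5, 5, 5); diag(half) <- 1
  expect_equal(pac_score(half), 1)
  expect_error(pac_score(half, lower = 0.9, upper = 0.1), "lower")
})

test_that("model-order selection keeps the largest reliable clustering", {
  maps <- blob_maps(5, list(1:8, 21:28, 41:48), noise = 0.05, seed = 5)
  cms <- lapply(2:5, function(k)
    consensus_matrix(maps, k, n_runs = 40, n_replicates = 5, seed = k))
  sel <- select_solution(cms, n_boot = 100, seed = 1)
  expect_equal(sel$k_selected, 3)
  single <- select_solution(cms[2], n_boot = 100, seed = 1)
  expect_equal(single$k_selected, 3)
  # near-uniform consensus values are consistent with unimodality -> fallback
  fake <- structure(list(values = {
    M <- matrix(0.5, 8, 8) + matrix(runif(64, -0.05, 0.05), 8)
    M <- (M + t(M)) / 2; diag(M) <- 1; M
  }, k = 2, n_runs = 10, subsample_fraction = 0.6), class = "consensus_matrix")
  expect_warning(fb <- select_solution(list(fake), n_boot = 100, seed = 2),
                 "unimodal|PAC")
  expect_equal(fb$k_selected, 2)
})

test_that("affinity propagation extracts block exemplars and is permutation-equivariant", {
  maps <- blob_maps(5, list(1:8, 21:28), noise = 0.03, seed = 6)
  cm <- consensus_matrix(maps, 2, n_runs = 40, n_replicates = 5, seed = 3)
  sol <- affinity_propagation_consensus(cm, 2)
  expect_equal(sol$k_selected, 2)
  expect_true(sol$achieved_target)
  expect_equal(length(unique(sol$assignments[1:5])), 1)
  expect_false(sol$assignments[1] == sol$assignments[6])
  # exemplars are members of their own cluster
  for (e in seq_along(sol$exemplars))
    expect_equal(sol$assignments[sol$exemplars[e]], e)
  # single subject: self-exemplar
  s1 <- affinity_propagation_consensus(matrix(1, 1, 1), 1)
  expect_equal(s1$assignments, 1L)
  expect_equal(s1$exemplars, 1L)
  # permutation equivariance of exemplar membership
  perm <- c(6:10, 1:5)
  cmp <- cm; cmp$values <- cm$values[perm, perm]
  solp <- affinity_propagation_consensus(cmp, 2)
  same_orig <- outer(sol$assignments, sol$assignments, `==`)
  same_perm <- outer(solp$assignments, solp$assignments, `==`)
  expect_identical(same_perm, same_orig[perm, perm])
})

test_that("within-cluster similarity exceeds between-cluster similarity on planted groups", {
  maps <- blob_maps(6, list(1:8, 21:28), noise = 0.05, seed = 8)
  assign <- rep(1:2, each = 6)
  s <- cluster_similarity_summary(maps, assign)
  expect_gt(s$mean_within, s$mean_between)
  expect_false(any(is.na(s$per_subject$contrast)))
  ident <- matrix(rep(c(1, 0, 1), 4), 4, 3, byrow = TRUE)
  s2 <- cluster_similarity_summary(ident, c(1, 1, 2, 2))
  expect_equal(s2$mean_within, 1)
  expect_equal(s2$mean_between, 1)
  expect_error(cluster_similarity_summary(maps, rep(1, 12)), "clusters")
})

test_that("doubling consensus runs changes PAC only marginally", {
  maps <- blob_maps(5, list(1:8, 21:28), noise = 0.25, seed = 9)
  p1 <- pac_score(consensus_matrix(maps, 2, n_runs = 100, n_replicates = 3, seed = 4))
  p2 <- pac_score(consensus_matrix(maps, 2, n_runs = 200, n_replicates = 3, seed = 4))
  expect_lt(abs(p1 - p2), 0.02 + 1e-9)
})
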
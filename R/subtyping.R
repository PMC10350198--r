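# Consensus clustering of saliency maps: eta-squared distance k-means over
# voxel subsamples, dip-test screening of consensus distributions, PAC
# model-order selection and affinity-propagation exemplar extraction.

#' Eta-squared similarity between two whole-brain maps
#'
#' Pointwise similarity penalizing scale and offset differences:
#' `eta2 = 1 - SS_within / SS_total` with per-voxel means `m_i = (a_i+b_i)/2`
#' and grand mean `M` over both maps;
#' `SS_within = sum((a_i-m_i)^2 + (b_i-m_i)^2)`,
#' `SS_total = sum((a_i-M)^2 + (b_i-M)^2)`. Identical maps score 1; maps
#' sharing no variance score 0. The clustering distance is `1 - eta2`.
#'
#' @param map_a,map_b numeric vectors (or arrays) of equal length >= 2
#' @return similarity in (-Inf, 1]
#' @export
eta_squared_similarity <- function(map_a, map_b) {
  a <- as.numeric(map_a); b <- as.numeric(map_b)
  if (length(a) != length(b) || length(a) < 2)
    stop_input("maps must have equal length >= 2")
  M <- mean(c(a, b))
  ss_total <- sum((a - M)^2) + sum((b - M)^2)
  if (ss_total == 0) stop_input("both maps constant: eta-squared undefined")
  m <- (a + b) / 2
  ss_within <- sum((a - m)^2) + sum((b - m)^2)   # = sum((a-b)^2)/2
  1 - ss_within / ss_total
}

# vectorized 1 - eta^2 distances between rows of X (n x V) and rows of C (k x V)
eta_dist_matrix <- function(X, C) {
  V <- ncol(X)
  ssx <- rowSums(X^2); mx <- rowMeans(X)
  ssc <- rowSums(C^2); mc <- rowMeans(C)
  cross <- X %*% t(C)                            # n x k
  ss_within <- 0.5 * (outer(ssx, ssc, `+`) - 2 * cross)
  Mg <- outer(mx, mc, `+`) / 2                   # grand means
  ss_total <- outer(ssx, ssc, `+`) - 2 * V * Mg^2
  ss_within / pmax(ss_total, 1e-24)
}

#' k-means clustering of maps under the eta-squared distance
#'
#' k-means++ seeding with assignment by minimal `1 - eta2` to the centroid
#' and arithmetic-mean centroid updates (relaxed k-means; a medoid update is
#' available via `medoid = TRUE`). The best of `n_replicates` restarts by
#' total distance is returned.
#'
#' @param maps subjects x voxels matrix
#' @param k number of clusters (1 <= k <= subjects)
#' @param n_replicates restarts (default 250)
#' @param seed integer seed
#' @param max_iter Lloyd iterations per replicate
#' @param medoid use medoid instead of mean centroid updates
#' @return list with `assignments`, `centroids`, `total_distance`,
#'   `replicate_distances`
#' @export
kmeans_eta <- function(maps, k, n_replicates = 250L, seed = 1L,
                       max_iter = 100L, medoid = FALSE) {
  n <- nrow(maps)
  if (k < 1) stop_input("k must be >= 1")
  if (k > n) stop_input("k exceeds the number of subjects")
  one_run <- function(rep_seed) {
    with_seed(rep_seed, {
      centers <- integer(k)
      centers[1] <- sample.int(n, 1)
      if (k > 1) for (j in 2:k) {
        d <- eta_dist_matrix(maps, maps[centers[1:(j - 1)], , drop = FALSE])
        dmin <- apply(d, 1, min)
        dmin[centers[1:(j - 1)]] <- 0
        if (sum(dmin) <= 0) centers[j] <- sample.int(n, 1)
        else centers[j] <- sample.int(n, 1, prob = pmax(dmin, 0))
      }
      C <- maps[centers, , drop = FALSE]
      assign_old <- rep(0L, n)
      for (it in seq_len(max_iter)) {
        D <- eta_dist_matrix(maps, C)
        assign_new <- max.col(-D, ties.method = "first")
        for (j in seq_len(k)) {
          members <- which(assign_new == j)
          if (!length(members)) {           # reseed empty cluster to farthest point
            far <- which.max(apply(D, 1, min))
            assign_new[far] <- j
            members <- far
          }
          if (medoid) {
            Dm <- eta_dist_matrix(maps[members, , drop = FALSE],
                                  maps[members, , drop = FALSE])
            C[j, ] <- maps[members[which.min(rowSums(Dm))], ]
          } else {
            C[j, ] <- colMeans(maps[members, , drop = FALSE])
          }
        }
        if (identical(assign_new, assign_old)) break
        assign_old <- assign_new
      }
      D <- eta_dist_matrix(maps, C)
      total <- sum(D[cbind(seq_len(n), assign_old)])
      list(assignments = assign_old, centroids = C, total_distance = total)
    })
  }
  runs <- lapply(seq_len(n_replicates), function(r) one_run(substream_seed(seed, "rep", r)))
  dists <- vapply(runs, `[[`, numeric(1), "total_distance")
  best <- runs[[which.min(dists)]]
  best$replicate_distances <- dists
  best
}

#' Consensus matrix over voxel subsamples
#'
#' Each run clusters all subjects on a random subset of voxels
#' (`subsample_fraction`, default 60%); the consensus entry `C_ij` is the
#' proportion of runs in which subjects i and j were co-clustered (subjects
#' are always present, so the denominator is `n_runs`). Diagonal set to 1.
#'
#' @param maps subjects x voxels matrix
#' @param k candidate cluster count
#' @param n_runs subsampling runs (default 1000)
#' @param subsample_fraction fraction of voxels per run (default 0.6)
#' @param n_replicates k-means restarts per run
#' @param seed integer seed
#' @return object of class `consensus_matrix` with fields `values`, `k`,
#'   `n_runs`, `subsample_fraction`
#' @export
consensus_matrix <- function(maps, k, n_runs = 1000L, subsample_fraction = 0.6,
                             n_replicates = 10L, seed = 1L) {
  if (n_runs < 1) stop_input("n_runs must be >= 1")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop_input("subsample_fraction must be in (0, 1]")
  n <- nrow(maps)
  V <- ncol(maps)
  counts <- matrix(0, n, n)
  for (r in seq_len(n_runs)) {
    vox <- with_seed(substream_seed(seed, "vox", r),
                     sample.int(V, max(2L, round(subsample_fraction * V))))
    km <- kmeans_eta(maps[, vox, drop = FALSE], k, n_replicates = n_replicates,
                     seed = substream_seed(seed, "km", r))
    counts <- counts + outer(km$assignments, km$assignments, `==`)
  }
  values <- counts / n_runs
  diag(values) <- 1
  structure(list(values = values, k = k, n_runs = n_runs,
                 subsample_fraction = subsample_fraction),
            class = "consensus_matrix")
}

# ---- Hartigan dip ----------------------------------------------------------

# lower convex hull touch indices of points (xs, ys), xs strictly increasing
lower_hull_idx <- function(xs, ys) {
  n <- length(xs)
  h <- integer(0)
  for (i in seq_len(n)) {
    while (length(h) >= 2) {
      a <- h[length(h) - 1]; b <- h[length(h)]
      if ((ys[b] - ys[a]) * (xs[i] - xs[a]) >= (ys[i] - ys[a]) * (xs[b] - xs[a]))
        h <- h[-length(h)] else break
    }
    h <- c(h, i)
  }
  h
}

#' Hartigan's dip statistic and bootstrap unimodality test
#'
#' Computes the dip -- the supremum distance between the empirical CDF and
#' the closest unimodal CDF, found by the iterative greatest-convex-minorant
#' / least-concave-majorant narrowing of the modal interval -- and a p-value
#' from a uniform-reference bootstrap (the least favourable unimodal null).
#'
#' @param values numeric vector, length >= 4
#' @param n_boot bootstrap replicates for the p-value (default 1000)
#' @param seed integer seed
#' @return list with `dip` and `p`
#' @export
dip_test <- function(values, n_boot = 1000L, seed = 1L) {
  if (length(values) < 4) stop_input("dip test requires >= 4 values")
  if (max(values) == min(values)) return(list(dip = 0, p = 1))
  d_obs <- dip_stat(values)
  n <- length(values)
  null <- with_seed(substream_seed(seed, "dipboot"), {
    vapply(seq_len(n_boot), function(i) dip_stat(stats::runif(n)), numeric(1))
  })
  list(dip = d_obs, p = (1 + sum(null >= d_obs)) / (1 + n_boot))
}

#' @rdname dip_test
#' @export
dip_stat <- function(values) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(0)
  lo <- 1L; hi <- n
  D <- 0
  for (iter in seq_len(100L)) {
    idx <- lo:hi
    ux <- unique(x[idx])
    if (length(ux) < 2) break
    first_i <- idx[match(ux, x[idx])]                 # first tied index per x
    last_i <- idx[length(idx) + 1L - match(ux, rev(x[idx]))]  # last tied index
    gh <- lower_hull_idx(ux, (first_i - 1) / n)       # GCM touchpoints
    lh <- lower_hull_idx(ux, -(last_i / n))           # LCM (upper hull)
    g <- first_i[gh]; l <- last_i[lh]
    gcm_at <- function(xq) stats::approx(ux[gh], (g - 1) / n, xout = xq,
                                         rule = 2)$y
    lcm_at <- function(xq) stats::approx(ux[lh], l / n, xout = xq,
                                         rule = 2)$y
    gap_g <- lcm_at(ux[gh]) - (g - 1) / n
    gap_l <- l / n - gcm_at(ux[lh])
    d <- max(c(gap_g, gap_l))
    if (d <= D) break
    if (max(gap_g) >= max(gap_l)) {
      ig <- g[which.max(gap_g)]
      cand <- l[l >= ig]
      ih <- if (length(cand)) min(cand) else hi
    } else {
      ih <- l[which.max(gap_l)]
      cand <- g[g <= ih]
      ig <- if (length(cand)) max(cand) else lo
    }
    dl <- max((lo:ig) / n - gcm_at(x[lo:ig]))
    du <- max(lcm_at(x[ih:hi]) - ((ih:hi) - 1) / n)
    D <- max(D, dl, du)
    if (ig >= ih || (ig == lo && ih == hi)) break
    lo <- ig; hi <- ih
  }
  D / 2
}

#' Proportion of ambiguously clustered pairs
#'
#' Fraction of off-diagonal upper-triangle consensus entries strictly inside
#' the interval `(lower, upper)`.
#'
#' @param consensus a `consensus_matrix` (or plain matrix)
#' @param lower,upper ambiguity interval (default 0.1, 0.9)
#' @return fraction in [0, 1]
#' @export
pac_score <- function(consensus, lower = 0.1, upper = 0.9) {
  if (lower >= upper) stop_input("lower must be < upper")
  C <- if (inherits(consensus, "consensus_matrix")) consensus$values else consensus
  v <- C[upper.tri(C)]
  mean(v > lower & v < upper)
}

#' Select the cluster count from candidate consensus matrices
#'
#' Candidates whose consensus-value distribution is consistent with
#' unimodality (dip p > `dip_alpha`: subjects are not consistently placed
#' together or apart) are excluded; among the survivors, the largest k with
#' PAC <= `pac_threshold` is selected (the most complex reliable solution).
#' If no survivor meets the PAC threshold, the survivor with minimal PAC is
#' returned with a warning.
#'
#' @param consensus_list named list of `consensus_matrix` objects (names or
#'   `$k` give the candidate cluster counts)
#' @param pac_threshold PAC reliability threshold (default 0.1)
#' @param dip_alpha dip screening level (default 0.05)
#' @param n_boot bootstrap replicates for each dip test
#' @param seed integer seed
#' @return list with `k_selected`, `pac`, `dip_p` and the per-candidate
#'   `table`
#' @export
select_solution <- function(consensus_list, pac_threshold = 0.1,
                            dip_alpha = 0.05, n_boot = 200L, seed = 1L) {
  if (!length(consensus_list)) stop_input("need at least one candidate solution")
  ks <- vapply(consensus_list, function(cm) cm$k, numeric(1))
  pac <- vapply(consensus_list, pac_score, numeric(1))
  dip_p <- vapply(seq_along(consensus_list), function(i) {
    v <- consensus_list[[i]]$values
    dip_test(v[upper.tri(v)], n_boot = n_boot,
             seed = substream_seed(seed, "dip", i))$p
  }, numeric(1))
  tab <- data.frame(k = ks, pac = pac, dip_p = dip_p,
                    unimodal_consistent = dip_p > dip_alpha)
  survivors <- which(!tab$unimodal_consistent)
  if (!length(survivors)) {
    warning("all candidates consistent with unimodality; falling back to min-PAC")
    survivors <- seq_along(ks)
  }
  ok <- survivors[pac[survivors] <= pac_threshold]
  if (length(ok)) {
    sel <- ok[which.max(ks[ok])]
  } else {
    warning("no candidate meets the PAC threshold; falling back to min-PAC survivor")
    sel <- survivors[which.min(pac[survivors])]
  }
  list(k_selected = ks[sel], pac = pac[sel], dip_p = dip_p[sel], table = tab)
}

# ---- affinity propagation --------------------------------------------------

affinity_propagation <- function(S, preference, damping = 0.9, max_iter = 2000L,
                                 conv_iter = 100L) {
  n <- nrow(S)
  diag(S) <- preference
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  stable <- 0L; last_ex <- NULL
  for (it in seq_len(max_iter)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS; AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0); diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (identical(ex, last_ex)) stable <- stable + 1L else stable <- 0L
    last_ex <- ex
    if (stable >= conv_iter && length(ex) > 0) break
  }
  if (!length(last_ex))
    stop_input("affinity propagation failed to converge; try lower damping or higher preference")
  exemplars <- last_ex
  assign_to <- apply(S[, exemplars, drop = FALSE], 1, which.max)
  assign_to[exemplars] <- seq_along(exemplars)
  list(exemplars = exemplars, assignments = assign_to, iterations = it)
}

#' Extract exemplar-based clusters from a consensus matrix
#'
#' Runs affinity propagation with the consensus values as similarities,
#' tuning the shared preference by bisection so the emergent cluster count
#' matches `target_k` (the nearest achievable count is returned with a flag
#' otherwise). Exemplar subjects represent each cluster.
#'
#' @param consensus a `consensus_matrix` (or plain similarity matrix)
#' @param target_k desired number of clusters
#' @param damping message damping (default 0.9)
#' @param max_bisect bisection steps on the preference
#' @return object of class `cluster_solution` with `assignments`,
#'   `exemplars`, `k_selected`, `achieved_target`
#' @export
affinity_propagation_consensus <- function(consensus, target_k, damping = 0.9,
                                           max_bisect = 20L) {
  S <- if (inherits(consensus, "consensus_matrix")) consensus$values else consensus
  n <- nrow(S)
  # deterministic tie-breaking jitter prevents message-passing oscillation
  # on exactly symmetric similarities
  jit <- with_seed(substream_seed(1L, "ap-jitter", n),
                   matrix(stats::runif(n * n), n, n))
  S <- S + 1e-8 * (jit + t(jit))
  if (n == 1)
    return(structure(list(assignments = 1L, exemplars = 1L, k_selected = 1L,
                          achieved_target = target_k == 1L),
                     class = "cluster_solution"))
  rng <- range(S[upper.tri(S)])
  p_lo <- rng[1] - 2 * (rng[2] - rng[1]) - 2    # strongly favours few clusters
  p_hi <- rng[2] + 2                            # favours many clusters
  run <- function(p) tryCatch(affinity_propagation(S, p, damping = damping),
                              error = function(e) NULL)
  best <- NULL
  for (i in seq_len(max_bisect)) {
    p_mid <- (p_lo + p_hi) / 2
    sol <- run(p_mid)
    if (is.null(sol)) { p_hi <- p_mid; next }
    kk <- length(sol$exemplars)
    if (is.null(best) || abs(kk - target_k) < abs(length(best$exemplars) - target_k))
      best <- sol
    if (kk == target_k) { best <- sol; break }
    if (kk < target_k) p_lo <- p_mid else p_hi <- p_mid
  }
  if (is.null(best)) stop_input("affinity propagation did not converge for any preference")
  structure(list(assignments = as.integer(best$assignments),
                 exemplars = as.integer(best$exemplars),
                 k_selected = length(best$exemplars),
                 achieved_target = length(best$exemplars) == target_k),
            class = "cluster_solution")
}

#' Within- versus between-cluster similarity summary
#'
#' Mean eta-squared similarity among members of the same cluster and across
#' clusters, plus the per-subject contrast (mean within minus mean between).
#' Singleton clusters have undefined within-similarity and are flagged.
#'
#' @param maps subjects x voxels matrix
#' @param assignments integer cluster labels (>= 2 clusters)
#' @return list with `mean_within`, `mean_between`, `per_subject` data frame
#'   and `singleton_clusters`
#' @export
cluster_similarity_summary <- function(maps, assignments) {
  ks <- sort(unique(assignments))
  if (length(ks) < 2) stop_input("need >= 2 clusters")
  n <- nrow(maps)
  sim <- 1 - eta_dist_matrix(maps, maps)
  diag(sim) <- NA
  same <- outer(assignments, assignments, `==`); diag(same) <- NA
  per <- data.frame(
    subject = seq_len(n),
    within = vapply(seq_len(n), function(i) mean(sim[i, which(same[i, ])]), numeric(1)),
    between = vapply(seq_len(n), function(i) mean(sim[i, which(!same[i, ])]), numeric(1)))
  per$contrast <- per$within - per$between
  singles <- ks[tabulate(match(assignments, ks)) == 1]
  list(mean_within = mean(sim[which(same)], na.rm = TRUE),
       mean_between = mean(sim[which(!same)], na.rm = TRUE),
       per_subject = per, singleton_clusters = singles)
}
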
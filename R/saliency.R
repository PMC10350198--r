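# Saliency attribution for the CNN and the SVM.
#
# Grad-CAM++ weighs last-convolution activation channels by second-order
# gradient terms (the usual elementwise gradient-power surrogate for the
# higher derivatives, exact for an exponential-activated class score).
# The signed deep attribution is a baselines-averaged path-gradient
# (expected-gradients style) estimator that preserves the completeness
# property: attributions sum to the score difference from the baselines.
# Kernel SHAP solves the Shapley-kernel weighted least squares over sampled
# coalitions with conditional nearest-neighbour imputation.

# trilinear upsampling of a 3D array to out_dims (voxel centres aligned)
trilinear_upsample <- function(arr, out_dims) {
  din <- dim(arr)
  if (identical(as.integer(din), as.integer(out_dims))) return(arr)
  coord <- function(ax) {
    s <- din[ax] / out_dims[ax]
    pmin(pmax((seq_len(out_dims[ax]) - 0.5) * s + 0.5, 1), din[ax])
  }
  cx <- coord(1); cy <- coord(2); cz <- coord(3)
  x0 <- pmin(floor(cx), din[1] - 1 + (din[1] == 1)); fx <- cx - x0
  y0 <- pmin(floor(cy), din[2] - 1 + (din[2] == 1)); fy <- cy - y0
  z0 <- pmin(floor(cz), din[3] - 1 + (din[3] == 1)); fz <- cz - z0
  x1 <- pmin(x0 + 1, din[1]); y1 <- pmin(y0 + 1, din[2]); z1 <- pmin(z0 + 1, din[3])
  out <- array(0, out_dims)
  gx <- list(list(x0, 1 - fx), list(x1, fx))
  gy <- list(list(y0, 1 - fy), list(y1, fy))
  gz <- list(list(z0, 1 - fz), list(z1, fz))
  for (a in gx) for (b in gy) for (cc in gz) {
    wt <- outer(outer(a[[2]], b[[2]]), cc[[2]])
    out <- out + wt * arr[a[[1]], b[[1]], cc[[1]], drop = FALSE]
  }
  out
}

# forward + gradient of the class logit w.r.t. the last-conv activations
cnn_conv_grad <- function(trained, x_row, class) {
  model <- trained$model
  fw <- nn_forward(model, matrix(x_row, nrow = 1), train = FALSE)
  onehot <- matrix(0, 1, ncol(fw$logits))
  onehot[1, class + 1L] <- 1
  bw <- nn_backward(fw, onehot, stop_at = model$last_conv_index,
                    need_param_grads = FALSE)
  pool_layer <- model$layers[[model$last_conv_index + 1L]]
  list(A = fw$caches$last_conv, G = bw$d_stop, dims = pool_layer$dims,
       logits = fw$logits, probs = fw$probs)
}

#' Grad-CAM++ saliency map for a CNN prediction
#'
#' Channel weights are `w_k = sum_vox(alpha_k * relu(dS/dA_k))` with
#' `alpha_k = G^2 / (2 G^2 + sum_vox(A_k) * G^3)` (gradient-power surrogate,
#' epsilon-guarded denominator); the map is `relu(sum_k w_k A_k)` trilinearly
#' upsampled to the input grid. Nonnegative by construction.
#'
#' @param trained a `trained_cnn`
#' @param x_row one subject's input map as a voxel vector
#' @param class class index (0/1) whose score is attributed; default the
#'   predicted class
#' @return list with `values` (nonnegative 3D array on the input grid),
#'   `method`, `predicted_class`, `sign_convention`
#' @export
grad_cam_pp <- function(trained, x_row, class = NULL) {
  if (is.null(class)) {
    fw <- nn_forward(trained$model, matrix(x_row, nrow = 1), train = FALSE)
    class <- max.col(fw$probs) - 1L
  }
  cg <- cnn_conv_grad(trained, x_row, class)
  A <- cg$A; G <- cg$G
  eps <- 1e-8
  if (all(abs(G) < 1e-14)) {
    warning("all-zero gradients: Grad-CAM++ map is zero")
    return(structure(list(values = array(0, trained$model$input_shape),
                          method = "grad_cam_pp", predicted_class = class,
                          sign_convention = "nonnegative"), class = "saliency_map"))
  }
  sumA <- colSums(A)
  denom <- 2 * G^2 + sweep(G^3, 2, sumA, `*`)
  denom <- denom + ifelse(denom >= 0, eps, -eps)
  alpha <- G^2 / denom
  alpha[!is.finite(alpha)] <- 0
  w <- colSums(alpha * pmax(G, 0))
  cam <- pmax(as.vector(A %*% w), 0)
  up <- trilinear_upsample(array(cam, cg$dims), trained$model$input_shape)
  structure(list(values = up, method = "grad_cam_pp", predicted_class = class,
                 sign_convention = "nonnegative"), class = "saliency_map")
}

# gradient of the class logit w.r.t. the input voxels, batched over rows of X
cnn_input_grad <- function(trained, X, class) {
  fw <- nn_forward(trained$model, X, train = FALSE)
  onehot <- matrix(0, nrow(X), ncol(fw$logits))
  onehot[cbind(seq_len(nrow(X)), class + 1L)] <- 1
  bw <- nn_backward(fw, onehot, need_input_grad = TRUE, need_param_grads = FALSE)
  list(grad = bw$d_input, logits = fw$logits)
}

cnn_class_score <- function(trained, X, class) {
  nn_forward(trained$model, X, train = FALSE)$logits[, class + 1L]
}

#' Baseline-referenced path-gradient attribution (signed)
#'
#' For each baseline b the straight-line path from b to the input is
#' integrated by an m-step midpoint rule:
#' `attr = (x - b) * mean_t grad f_c(b + t (x - b))`, averaged over
#' baselines. Attributions approximately satisfy completeness:
#' `sum(attr) ~ f_c(x) - mean_b f_c(b)`.
#'
#' @param trained a `trained_cnn`
#' @param x_row input voxel vector
#' @param class class index (0/1) to attribute
#' @param baselines matrix of baseline volumes (rows), e.g. an all-background
#'   map plus training-set references
#' @param m_steps path integration steps (default 64; 16 steps leave
#'   completeness errors of a few percent on ReLU networks)
#' @return list with signed `values` (3D array), `method`, `completeness_gap`
#' @export
deep_attribution <- function(trained, x_row, class, baselines, m_steps = 64L) {
  if (is.null(dim(baselines))) baselines <- matrix(baselines, nrow = 1)
  if (!nrow(baselines)) stop_input("at least one baseline volume is required")
  V <- length(x_row)
  attr <- numeric(V)
  for (bi in seq_len(nrow(baselines))) {
    b <- baselines[bi, ]
    diff <- x_row - b
    ts <- (seq_len(m_steps) - 0.5) / m_steps
    Xp <- t(vapply(ts, function(t) b + t * diff, numeric(V)))
    g <- cnn_input_grad(trained, Xp, rep(class, m_steps))$grad
    attr <- attr + diff * colMeans(g)
  }
  attr <- attr / nrow(baselines)
  f_x <- cnn_class_score(trained, matrix(x_row, 1), class)
  f_b <- mean(cnn_class_score(trained, baselines, class))
  structure(list(values = array(attr, trained$model$input_shape),
                 method = "deep_attr", predicted_class = class,
                 sign_convention = "signed",
                 completeness_gap = sum(attr) - (f_x - f_b)),
            class = "saliency_map")
}

# Shapley kernel weight for a coalition of size s out of M features
shapley_kernel_weight <- function(M, s) {
  (M - 1) / (choose(M, s) * s * (M - s))
}

# value function: conditional expectation with absent features imputed from
# the instance's k nearest background neighbours
shap_value_function <- function(predict_fun, instance, neighbors) {
  function(z) {            # z: logical inclusion vector
    syn <- neighbors
    syn[, z] <- matrix(instance[z], nrow(neighbors), sum(z), byrow = TRUE)
    mean(predict_fun(syn))
  }
}

#' Kernel SHAP attributions with conditional nearest-neighbour imputation
#'
#' Samples feature coalitions (or enumerates all of them when feasible),
#' evaluates each coalition by imputing absent features from the k nearest
#' background neighbours of the instance (k = ceil(knn_fraction * n)), and
#' solves the Shapley-kernel weighted least squares under the efficiency
#' constraint `sum(phi) = f(x) - mean_b f(b)`.
#'
#' @param predict_fun function(matrix) -> numeric model outputs
#' @param instance feature vector to explain
#' @param background background sample matrix (>= 10 rows)
#' @param n_coalitions Monte-Carlo coalition budget; coalitions are
#'   enumerated exhaustively when `2^M - 2 <= n_coalitions`
#' @param knn_fraction fraction of background used as neighbours (default 0.1)
#' @param seed integer seed
#' @return list with `phi` (signed attributions), `base_value`, `fx`
#' @export
kernel_shap <- function(predict_fun, instance, background, n_coalitions = 2048L,
                        knn_fraction = 0.1, seed = 1L) {
  M <- length(instance)
  n_bg <- nrow(background)
  if (n_bg < 10) stop_input("background must contain at least 10 samples")
  k <- max(1L, ceiling(knn_fraction * n_bg))
  d2 <- colSums((t(background) - instance)^2)
  neighbors <- background[order(d2)[seq_len(k)], , drop = FALSE]
  v <- shap_value_function(predict_fun, instance, neighbors)
  fx <- mean(predict_fun(matrix(instance, 1)))
  f0 <- mean(predict_fun(neighbors))
  if (abs(fx - f0) < 1e-15 && stats::sd(predict_fun(background)) < 1e-15) {
    return(list(phi = numeric(M), base_value = f0, fx = fx, constant = TRUE))
  }
  exhaustive <- (2^M - 2) <= n_coalitions
  if (exhaustive) {
    Z <- matrix(FALSE, 2^M - 2, M)
    for (i in seq_len(2^M - 2))
      Z[i, ] <- as.logical(bitwAnd(i, 2^(seq_len(M) - 1)) > 0)
  } else {
    Z <- with_seed(substream_seed(seed, "coal"), {
      sizes <- 1:(M - 1)
      pw <- vapply(sizes, function(s) shapley_kernel_weight(M, s) * choose(M, s),
                   numeric(1))
      ssamp <- sample(sizes, n_coalitions, replace = TRUE, prob = pw)
      t(vapply(ssamp, function(s) {
        z <- logical(M); z[sample.int(M, s)] <- TRUE; z
      }, logical(M)))
    })
  }
  wts <- vapply(rowSums(Z), function(s) shapley_kernel_weight(M, s), numeric(1))
  vz <- vapply(seq_len(nrow(Z)), function(i) v(Z[i, ]), numeric(1))
  # eliminate the efficiency constraint: phi_M = fx - f0 - sum(phi_1..M-1)
  y <- vz - f0 - Z[, M] * (fx - f0)
  A <- Z[, -M, drop = FALSE] - Z[, M]
  W <- wts
  AtW <- t(A * W)
  AtWA <- AtW %*% A
  rhs <- AtW %*% y
  # Monte-Carlo designs at high feature counts can be numerically singular;
  # fall back to a relative ridge, then to the pseudoinverse
  phi_part <- tryCatch(solve(AtWA, rhs), error = function(e) {
    lam <- 1e-8 * (1 + mean(diag(AtWA)))
    tryCatch(solve(AtWA + diag(lam, M - 1), rhs),
             error = function(e2) MASS::ginv(AtWA + diag(lam, M - 1)) %*% rhs)
  })
  phi <- c(phi_part, fx - f0 - sum(phi_part))
  list(phi = as.numeric(phi), base_value = f0, fx = fx, constant = FALSE)
}

#' Normalize a saliency map to unit sum over brain voxels
#'
#' @param map a `saliency_map` (or 3D array)
#' @param zero_negatives replace negative values with zero before
#'   normalizing (as done for signed SHAP maps)
#' @param brain_mask optional logical array restricting the normalizing sum
#' @return `saliency_map` whose values sum to 1 over the brain
#' @export
normalize_saliency <- function(map, zero_negatives = FALSE, brain_mask = NULL) {
  vals <- if (inherits(map, "saliency_map")) map$values else map
  if (any(!is.finite(vals))) stop_input("saliency map contains non-finite values")
  if (zero_negatives) vals <- pmax(vals, 0)
  total <- if (is.null(brain_mask)) sum(vals) else sum(vals[brain_mask])
  if (total <= 0) stop_input("cannot normalize: map sums to zero after truncation")
  vals <- vals / total
  if (inherits(map, "saliency_map")) { map$values <- vals; map$normalized <- TRUE; map }
  else vals
}

#' Build lesion-centred regions of interest and their homologues
#'
#' Left-hemisphere ROIs partition the left brain: the lesion, a perilesional
#' ring (`ring_width` dilation steps around the lesion), and the remaining
#' extralesional tissue. Right-hemisphere homologues are the sagittal
#' mirrors of the left ROIs intersected with the brain mask.
#'
#' @param lesion_mask logical array within the left hemisphere
#' @param brain_mask logical brain array
#' @param left_mask logical left-hemisphere array
#' @param ring_width_voxels dilation steps for the perilesional ring
#'   (default 1; 0 gives an empty ring)
#' @return list of six logical masks: `lesion`, `perilesional`,
#'   `extralesional`, `lesion_homologue`, `perilesional_homologue`,
#'   `extralesional_homologue`
#' @export
build_rois <- function(lesion_mask, brain_mask, left_mask, ring_width_voxels = 1L) {
  if (any(lesion_mask & !left_mask))
    stop_input("lesion must lie within the left hemisphere")
  dil <- lesion_mask
  if (ring_width_voxels > 0)
    for (i in seq_len(ring_width_voxels)) dil <- dilate6(dil)
  peri <- dil & !lesion_mask & left_mask & brain_mask
  extra <- left_mask & brain_mask & !lesion_mask & !peri
  if (!any(extra)) warning("lesion covers the whole left hemisphere: empty extralesional ROI")
  list(lesion = lesion_mask,
       perilesional = peri,
       extralesional = extra,
       lesion_homologue = mirror_x(lesion_mask) & brain_mask,
       perilesional_homologue = mirror_x(peri) & brain_mask,
       extralesional_homologue = mirror_x(extra) & brain_mask)
}

#' Common non-lesioned field of a subject group
#'
#' Voxels lesioned in any subject of the group (optionally dilated to cover
#' the convolutional halo of the lesion) carry lesion-anatomy variance rather
#' than atrophy information; clustering and decoding of saliency maps are
#' restricted to their complement, the field that is lesion-free in every
#' subject.
#'
#' @param features subjects x voxels matrix of scaled ordinal maps
#' @param dims 3D grid dimensions
#' @param lesion_value scaled code marking lesion voxels (default 1)
#' @param dilate dilation steps applied to the union lesion (default 1)
#' @return integer vector of retained voxel indices
#' @export
common_nonlesion_field <- function(features, dims, lesion_value = 1, dilate = 1L) {
  les_any <- array(FALSE, dims)
  for (i in seq_len(nrow(features)))
    les_any <- les_any | array(features[i, ] == lesion_value, dims)
  if (dilate > 0) for (d in seq_len(dilate)) les_any <- dilate6(les_any)
  which(!as.vector(les_any))
}

#' Per-subject saliency feature matrix restricted to a voxel field
#'
#' Flattens a list of saliency maps into a subjects x voxels matrix over the
#' given voxel field, normalizing each row to unit sum.
#'
#' @param maps list of `saliency_map`s (or 3D arrays)
#' @param field integer voxel indices (e.g. from [common_nonlesion_field()])
#' @return subjects x length(field) matrix with unit row sums
#' @export
saliency_feature_matrix <- function(maps, field) {
  m <- do.call(rbind, lapply(maps, function(s) {
    v <- as.numeric(if (inherits(s, "saliency_map")) s$values else s)[field]
    v / max(sum(v), 1e-12)
  }))
  m
}

#' Contrast mean ROI saliency between predicted classes
#'
#' For each ROI, averages the normalized saliency inside the ROI per subject
#' and compares severe vs nonsevere predictions with a two-sample t-test.
#' Empty ROIs are skipped with a flag.
#'
#' @param maps list of normalized saliency arrays (or `saliency_map`s),
#'   one per subject; ROIs may be per-subject (list of ROI sets) or shared
#' @param rois a single ROI set from [build_rois()] or a list of them
#' @param classes 0/1 predicted labels, >= 2 subjects per class
#' @return data frame with per-ROI class means, t statistic and p value
#' @export
roi_contrast <- function(maps, rois, classes) {
  tab <- table(classes)
  if (length(tab) < 2 || min(tab) < 2)
    stop_input("need >= 2 subjects per class in both classes")
  per_subject <- is.list(rois[[1]]) && !is.null(rois[[1]]$lesion)
  roi_names <- if (per_subject) names(rois[[1]]) else names(rois)
  out <- NULL
  for (rn in roi_names) {
    vals <- vapply(seq_along(maps), function(i) {
      m <- if (inherits(maps[[i]], "saliency_map")) maps[[i]]$values else maps[[i]]
      mask <- if (per_subject) rois[[i]][[rn]] else rois[[rn]]
      if (!any(mask)) return(NA_real_)
      mean(m[mask])
    }, numeric(1))
    if (all(is.na(vals))) {
      out <- rbind(out, data.frame(roi = rn, mean_severe = NA, mean_nonsevere = NA,
                                   t = NA, p = NA, skipped = TRUE))
      next
    }
    sv <- vals[classes == 1]; ns <- vals[classes == 0]
    tt <- tryCatch(stats::t.test(sv, ns), error = function(e) NULL)
    out <- rbind(out, data.frame(roi = rn,
                                 mean_severe = mean(sv, na.rm = TRUE),
                                 mean_nonsevere = mean(ns, na.rm = TRUE),
                                 t = if (is.null(tt)) NA else unname(tt$statistic),
                                 p = if (is.null(tt)) NA else tt$p.value,
                                 skipped = FALSE))
  }
  out
}
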
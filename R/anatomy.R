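#' Build a mirror-symmetric template brain
#'
#' Constructs an idealized template anatomy on a regular voxel grid: an
#' ellipsoidal brain with a CSF shell, a grey-matter ribbon and a white-matter
#' core, split into left/right hemispheres at the midsagittal plane. All
#' generated subjects share this template, mimicking group data registered to
#' a common space.
#'
#' @param grid_shape integer vector of 3 voxel counts (each even, >= 16)
#' @param voxel_size_mm isotropic voxel edge length in mm
#' @param seed integer; reserved for future stochastic templates, the default
#'   template is fully deterministic
#' @return list with logical 3D arrays `csf`, `gm`, `wm`, `brain`, `left`,
#'   `right`, plus `grid_shape` and `voxel_size_mm`
#' @export
build_anatomy_template <- function(grid_shape, voxel_size_mm = 2, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3) stop_input("grid_shape must have 3 dimensions")
  if (any(grid_shape < 16)) stop_input("grid too small: every axis must be >= 16 voxels")
  if (any(grid_shape %% 2 != 0)) stop_input("grid dimensions must be even")

  dm <- grid_shape
  ctr <- (dm + 1) / 2            # symmetric centre for even dims
  rad <- dm / 2 - 1.5            # leave a background margin
  ax <- (seq_len(dm[1]) - ctr[1]) / rad[1]
  ay <- (seq_len(dm[2]) - ctr[2]) / rad[2]
  az <- (seq_len(dm[3]) - ctr[3]) / rad[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  rho <- sqrt(r2)

  brain <- rho <= 1
  wm  <- rho <= 0.62
  gm  <- rho > 0.62 & rho <= 0.88
  csf <- rho > 0.88 & rho <= 1
  if (!any(wm) || !any(gm) || !any(csf))
    stop_input("grid too small to contain CSF shell, GM ribbon and WM core")

  left <- array(FALSE, dm)
  left[seq_len(dm[1] / 2), , ] <- TRUE
  list(csf = csf, gm = gm, wm = wm, brain = brain,
       left = left & brain, right = !left & brain,
       grid_shape = dm, voxel_size_mm = voxel_size_mm)
}

# Deterministic full growth order for a lesion from a perisylvian-analog seed
# point; the lesion at any size is a prefix of this order, which makes volume
# monotone in the size quantile by construction.
lesion_growth_order <- function(template, cap, seed) {
  dm <- template$grid_shape
  allowed <- template$left
  start_target <- c(0.25 * dm[1], 0.5 * dm[2], 0.55 * dm[3])
  cand <- which(allowed)
  ijk <- lin_to_ijk(cand, dm)
  d0 <- sqrt(colSums((t(ijk) - start_target)^2))
  start <- cand[which.min(d0)]

  in_lesion <- logical(prod(dm))
  in_frontier <- logical(prod(dm))
  # distance of every allowed voxel to the seed point, computed once
  sijk <- lin_to_ijk(start, dm)[1, ]
  dist_all <- numeric(prod(dm))
  dist_all[cand] <- sqrt(colSums((t(ijk) - sijk)^2))
  wt_all <- exp(-dist_all / 0.75) + 1e-12
  order_out <- integer(cap)
  nvox <- prod(dm)
  # stride offsets suffice: the brain keeps a background margin, so any
  # wrap-around neighbour falls outside the allowed mask and is filtered
  offs <- c(-1L, 1L, -dm[1], dm[1], -dm[1] * dm[2], dm[1] * dm[2])
  with_seed(seed, {
    order_out[1] <- start
    in_lesion[start] <- TRUE
    frontier <- start + offs
    frontier <- frontier[frontier >= 1L & frontier <= nvox]
    frontier <- frontier[allowed[frontier]]
    in_frontier[frontier] <- TRUE
    flen <- length(frontier)
    # exponential-race keys: picking the minimal key is a weighted draw,
    # with weights favouring voxels close to the seed (compact blobs)
    keys <- stats::rexp(flen) / wt_all[frontier]
    frontier <- c(frontier, integer(1024))
    keys <- c(keys, numeric(1024))
    n <- 1L
    while (n < cap && flen > 0) {
      pi <- which.min(keys[seq_len(flen)])
      pick <- frontier[pi]
      frontier[pi] <- frontier[flen]
      keys[pi] <- keys[flen]
      flen <- flen - 1L
      n <- n + 1L
      order_out[n] <- pick
      in_lesion[pick] <- TRUE
      in_frontier[pick] <- FALSE
      nb <- pick + offs
      nb <- nb[nb >= 1L & nb <= nvox]
      nb <- nb[allowed[nb] & !in_lesion[nb] & !in_frontier[nb]]
      if (length(nb)) {
        in_frontier[nb] <- TRUE
        if (flen + length(nb) > length(frontier)) {
          frontier <- c(frontier, integer(length(frontier)))
          keys <- c(keys, numeric(length(keys)))
        }
        frontier[flen + seq_along(nb)] <- nb
        keys[flen + seq_along(nb)] <- stats::rexp(length(nb)) / wt_all[nb]
        flen <- flen + length(nb)
      }
    }
    order_out[seq_len(n)]
  })
}

#' Sample a left-hemisphere lesion mask
#'
#' Grows a connected lesion blob from a fixed perisylvian-analog seed point in
#' the left hemisphere, emulating middle-cerebral-artery-territory strokes.
#' For a given seed the growth order is fixed, so lesion volume is monotone in
#' `size_quantile`.
#'
#' @param template output of [build_anatomy_template()]
#' @param size_quantile fraction in [0, 1] controlling lesion volume;
#'   0 gives a single-voxel lesion
#' @param seed integer RNG seed for the growth realization
#' @return logical 3D lesion mask confined to the left hemisphere
#' @export
sample_lesion_mask <- function(template, size_quantile, seed = 1L) {
  if (size_quantile < 0 || size_quantile > 1)
    stop_input("size_quantile must be in [0, 1]")
  n_left <- sum(template$left)
  cap <- max(1L, as.integer(round(0.25 * n_left)))
  target <- 1L + as.integer(floor(size_quantile * (cap - 1L)))
  if (target > n_left) {
    warning("requested lesion volume exceeds left-hemisphere brain volume; capped")
    target <- n_left
  }
  ord <- lesion_growth_order(template, cap, seed)
  target <- min(target, length(ord))
  mask <- array(FALSE, template$grid_shape)
  mask[ord[seq_len(target)]] <- TRUE
  mask
}

#' Generate planted atrophy subtype patterns
#'
#' Each subtype is a probability map built from a mixture of 2-4 Gaussian
#' blobs placed at well-separated grey-matter locations (farthest-point
#' seeding); even-numbered subtypes receive a mirrored contralateral blob so
#' that some patterns are bilateral.
#'
#' @param template output of [build_anatomy_template()]
#' @param n_subtypes number of patterns to plant
#' @param seed integer RNG seed
#' @param sigma_vox Gaussian blob width in voxels
#' @return list of 3D arrays in [0, 1], one per subtype
#' @export
make_subtype_patterns <- function(template, n_subtypes, seed = 1L, sigma_vox = NULL) {
  dm <- template$grid_shape
  if (is.null(sigma_vox)) sigma_vox <- max(3, round(min(dm) / 5))
  gm_idx <- which(template$gm & template$left)
  ijk <- lin_to_ijk(gm_idx, dm)
  with_seed(substream_seed(seed, "patterns"), {
    # farthest-point sampling of primary centres for separation across subtypes
    centers <- matrix(0, n_subtypes, 3)
    first <- ijk[sample.int(nrow(ijk), 1), ]
    centers[1, ] <- first
    if (n_subtypes > 1) {
      dmin <- sqrt(colSums((t(ijk) - first)^2))
      for (s in 2:n_subtypes) {
        pick <- which.max(dmin)
        centers[s, ] <- ijk[pick, ]
        dmin <- pmin(dmin, sqrt(colSums((t(ijk) - centers[s, ])^2)))
      }
    }
    coords <- lin_to_ijk(seq_len(prod(dm)), dm)
    patterns <- vector("list", n_subtypes)
    for (s in seq_len(n_subtypes)) {
      n_blobs <- sample(2:4, 1)
      blob_centers <- matrix(0, n_blobs, 3)
      blob_centers[1, ] <- centers[s, ]
      for (b in seq_len(n_blobs)[-1]) {
        blob_centers[b, ] <- centers[s, ] + round(stats::rnorm(3, 0, sigma_vox * 2))
      }
      if (s %% 2 == 0) {
        # bilateral pattern: mirror the primary blob into the right hemisphere
        mir <- centers[s, ]
        mir[1] <- dm[1] + 1 - mir[1]
        blob_centers <- rbind(blob_centers, mir)
      }
      pat <- numeric(prod(dm))
      for (b in seq_len(nrow(blob_centers))) {
        d2 <- colSums((t(coords) - blob_centers[b, ])^2)
        pat <- pmax(pat, exp(-d2 / (2 * sigma_vox^2)))
      }
      patterns[[s]] <- array(pat, dm)
    }
    patterns
  })
}

#' Apply subtype-specific atrophy to tissue masks
#'
#' Converts grey-matter voxels to CSF with probability
#' `min(1, burden * pattern)` at each voxel, simulating regionally patterned
#' atrophy whose total extent scales with a subject-level burden.
#'
#' @param tissue_masks list with logical arrays `csf`, `gm`, `wm`
#' @param subtype_pattern 3D probability map, same grid as the masks
#' @param burden nonnegative scalar scaling the conversion probability
#' @param seed integer RNG seed
#' @return list with modified `csf`/`gm`/`wm` masks and `n_converted`
#' @export
apply_subtype_atrophy <- function(tissue_masks, subtype_pattern, burden, seed = 1L) {
  if (burden < 0) stop_input("burden must be nonnegative")
  if (!identical(dim(subtype_pattern), dim(tissue_masks$gm)))
    stop_input("subtype_pattern shape does not match the tissue grid")
  gm_idx <- which(tissue_masks$gm)
  p <- pmin(1, burden * subtype_pattern[gm_idx])
  conv <- with_seed(seed, stats::runif(length(gm_idx)) < p)
  out <- tissue_masks
  conv_idx <- gm_idx[conv]
  out$gm[conv_idx] <- FALSE
  out$csf[conv_idx] <- TRUE
  out$n_converted <- length(conv_idx)
  out
}
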
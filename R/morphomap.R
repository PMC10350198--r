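#' @name morphomap
#' @title Ordinal morphometry maps
#' @description
#' The classifier input is a single-channel ordinal map that merges the three
#' binary tissue segmentations and the lesion mask into one grid of tissue
#' codes (background 0, CSF 1, GM 2, WM 3, lesion 4, lesion superseding any
#' tissue), downsampled by modal pooling, cropped to the cohort's common
#' field of view, and linearly scaled to [-1, 1].
NULL

default_code_table <- c(background = 0, csf = 1, gm = 2, wm = 3, lesion = 4)

new_ordinal_map <- function(values, voxel_size_mm, scaled = FALSE,
                            code_table = default_code_table) {
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 scaled = scaled, code_table = code_table),
            class = "ordinal_map")
}

#' Compose an ordinal morphometry map from tissue and lesion masks
#'
#' Every voxel receives exactly one code; the lesion code overrides any
#' tissue code, and voxels in no mask are background.
#'
#' @param tissue_masks list with logical arrays `csf`, `gm`, `wm` on one grid
#' @param lesion_mask logical array on the same grid
#' @param voxel_size_mm voxel size of the input grid (mm)
#' @param code_table named code mapping; defaults to
#'   background 0 < CSF 1 < GM 2 < WM 3 < lesion 4 (ordered by tissue density)
#' @return unscaled `ordinal_map`
#' @export
compose_ordinal_map <- function(tissue_masks, lesion_mask, voxel_size_mm = 2,
                                code_table = default_code_table) {
  dm <- dim(tissue_masks$gm)
  for (m in list(tissue_masks$csf, tissue_masks$wm, lesion_mask))
    if (!identical(dim(m), dm)) stop_input("masks must share one grid")
  v <- array(code_table[["background"]], dm)
  v[tissue_masks$csf] <- code_table[["csf"]]
  v[tissue_masks$gm] <- code_table[["gm"]]
  v[tissue_masks$wm] <- code_table[["wm"]]
  v[lesion_mask] <- code_table[["lesion"]]
  new_ordinal_map(v, voxel_size_mm, scaled = FALSE, code_table = code_table)
}

#' Downsample an ordinal map by modal pooling
#'
#' Each output voxel takes the modal (majority) code of its `factor`^3 input
#' block -- the block analog of nearest-neighbour interpolation for label
#' maps. Ties are broken toward the highest code so a lesion never disappears
#' on a tie. Trailing partial blocks are pooled over the available voxels.
#'
#' @param map unscaled `ordinal_map`
#' @param factor integer downsampling factor (>= 1)
#' @return `ordinal_map` at `factor`-times coarser grid
#' @export
downsample_mode <- function(map, factor) {
  stopifnot(inherits(map, "ordinal_map"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop_input("factor must be an integer >= 1")
  if (factor == 1) return(map)
  v <- map$values
  dm <- dim(v)
  out_dm <- as.integer(ceiling(dm / factor))
  codes <- sort(unname(map$code_table))
  # count occurrences of each code per block via padded block sums
  pad_dm <- out_dm * factor
  counts <- vector("list", length(codes))
  for (ci in seq_along(codes)) {
    ind <- array(0, pad_dm)
    ind[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- (v == codes[ci]) * 1
    # sum over factor^3 blocks by folding each axis
    a <- ind
    dim(a) <- c(factor, out_dm[1], factor, out_dm[2], factor, out_dm[3])
    counts[[ci]] <- apply(a, c(2, 4, 6), sum)
  }
  best <- array(codes[1], out_dm)
  best_n <- counts[[1]]
  for (ci in seq_along(codes)[-1]) {      # ascending codes: ties go to higher code
    take <- counts[[ci]] >= best_n
    best[take] <- codes[ci]
    best_n <- pmax(best_n, counts[[ci]])
  }
  new_ordinal_map(best, map$voxel_size_mm * factor, scaled = map$scaled,
                  code_table = map$code_table)
}

#' Crop a cohort of maps to the tightest common field of view
#'
#' Finds the tightest bounding box containing every nonzero voxel of every
#' map and applies the identical box to all maps.
#'
#' @param maps list of `ordinal_map`s sharing one grid
#' @return list with `maps` (cropped) and `bbox` (per-axis index ranges)
#' @export
crop_common_fov <- function(maps) {
  dm <- dim(maps[[1]]$values)
  nz <- array(FALSE, dm)
  for (m in maps) {
    if (!identical(dim(m$values), dm)) stop_input("all maps must share a grid")
    nz <- nz | (m$values != 0)
  }
  if (!any(nz)) stop_input("cannot crop: every map is all-zero")
  idx <- which(nz)
  ijk <- lin_to_ijk(idx, dm)
  bbox <- apply(ijk, 2, range)
  cropped <- lapply(maps, function(m) {
    m$values <- m$values[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2],
                         bbox[1, 3]:bbox[2, 3], drop = FALSE]
    m
  })
  list(maps = cropped, bbox = bbox)
}

#' Scale an ordinal map to the range [-1, 1]
#'
#' Linear map of code c to 2c/max_code - 1, so background maps to -1 and the
#' lesion code to 1. Refuses already-scaled input.
#'
#' @param map unscaled `ordinal_map`
#' @return scaled `ordinal_map`
#' @export
scale_to_range <- function(map) {
  stopifnot(inherits(map, "ordinal_map"))
  if (isTRUE(map$scaled)) stop_input("map is already scaled")
  cmax <- max(map$code_table)
  map$values <- 2 * map$values / cmax - 1
  map$scaled <- TRUE
  map
}

#' Write a 3D volume as NIfTI with voxel size in the header
#' @param values numeric or logical 3D array
#' @param voxel_size_mm isotropic voxel size (mm)
#' @param path output path (`.nii` or `.nii.gz`)
#' @export
write_volume_nifti <- function(values, voxel_size_mm, path) {
  img <- RNifti::asNifti(values + 0, reference = NULL)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D volume written by [write_volume_nifti()]
#' @param path NIfTI file path
#' @return list with `values` (3D array) and `voxel_size_mm`
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim(img)),
       voxel_size_mm = RNifti::pixdim(img)[1])
}

#' Preprocess the intact template through the same chain as the cohort
#'
#' Composes the lesion-free, atrophy-free template anatomy into an ordinal
#' map, downsamples it and applies the cohort's crop box and scaling. The
#' result is the natural reference volume for baseline-referenced saliency:
#' attribution against it localizes on each subject's pathology (lesion and
#' atrophy) rather than on shared anatomy.
#'
#' @param template output of [build_anatomy_template()]
#' @param factor downsampling factor used for the cohort
#' @param bbox crop box from [preprocess_cohort()]
#' @return scaled `ordinal_map` on the cropped cohort grid
#' @export
template_ordinal_map <- function(template, factor, bbox) {
  m <- downsample_mode(compose_ordinal_map(template[c("csf", "gm", "wm")],
                                           array(FALSE, template$grid_shape),
                                           template$voxel_size_mm), factor)
  m$values <- m$values[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2],
                       bbox[1, 3]:bbox[2, 3], drop = FALSE]
  scale_to_range(m)
}

# Flatten a list of maps to a subjects x voxels feature matrix
maps_to_matrix <- function(maps) {
  do.call(rbind, lapply(maps, function(m) as.numeric(m$values)))
}

#' Run the full preprocessing chain on a cohort
#'
#' Compose per-subject ordinal maps, downsample by modal pooling, crop to the
#' common field of view and scale to [-1, 1].
#'
#' @param cohort output of [generate_cohort()]
#' @param factor downsampling factor (4 turns 2 mm input into 8 mm maps)
#' @return list with `maps` (scaled ordinal maps), `bbox`, `dims` of the
#'   cropped grid, and `features` (subjects x voxels matrix)
#' @export
preprocess_cohort <- function(cohort, factor = 4) {
  maps <- lapply(cohort$subjects, function(s)
    downsample_mode(compose_ordinal_map(s$tissue_masks, s$lesion_mask,
                                        cohort$spec$voxel_size_mm), factor))
  cr <- crop_common_fov(maps)
  scaled <- lapply(cr$maps, scale_to_range)
  names(scaled) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  feat <- maps_to_matrix(scaled)
  rownames(feat) <- names(scaled)
  list(maps = scaled, bbox = cr$bbox, dims = dim(scaled[[1]]$values),
       features = feat)
}
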
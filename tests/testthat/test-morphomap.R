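make_masks <- function(dm = c(8L, 8L, 8L)) {
  csf <- array(FALSE, dm); gm <- array(FALSE, dm); wm <- array(FALSE, dm)
  csf[1:2, , ] <- TRUE; gm[3:5, , ] <- TRUE; wm[6:8, , ] <- TRUE
  list(csf = csf, gm = gm, wm = wm)
}

test_that("ordinal composition assigns one code per voxel with lesion superseding", {
  masks <- make_masks()
  lesion <- array(FALSE, c(8L, 8L, 8L)); lesion[3:4, 1:2, 1:2] <- TRUE
  m <- compose_ordinal_map(masks, lesion)
  expect_true(all(m$values %in% 0:4))
  expect_equal(m$values[3, 1, 1], 4)                  # GM voxel overridden by lesion
  expect_equal(sum(m$values == 4), sum(lesion))       # override is total
  empty <- compose_ordinal_map(masks, array(FALSE, c(8L, 8L, 8L)))
  expect_equal(sum(empty$values == 4), 0)
  expect_error(compose_ordinal_map(masks, array(FALSE, c(4L, 4L, 4L))), "grid")
})

test_that("modal downsampling pools by majority with ties toward the lesion", {
  dm <- c(4L, 4L, 4L)
  # 40 voxels of GM vs 24 of lesion -> GM wins
  v <- array(2, dm); v[seq_len(24)] <- 4
  m <- structure(list(values = v, voxel_size_mm = 2, scaled = FALSE,
                      code_table = c(background = 0, csf = 1, gm = 2, wm = 3, lesion = 4)),
                 class = "ordinal_map")
  expect_equal(downsample_mode(m, 4)$values[1, 1, 1], 2)
  # exact tie 32 vs 32 -> highest code (lesion) wins
  v2 <- array(2, dm); v2[seq_len(32)] <- 4
  m2 <- m; m2$values <- v2
  expect_equal(downsample_mode(m2, 4)$values[1, 1, 1], 4)
  expect_identical(downsample_mode(m, 1), m)
  expect_equal(downsample_mode(m, 4)$voxel_size_mm, 8)
  expect_error(downsample_mode(m, 0), "factor")
  # trailing partial blocks are pooled over available voxels
  v3 <- array(1, c(5L, 4L, 4L))
  m3 <- m; m3$values <- v3
  expect_equal(dim(downsample_mode(m3, 4)$values), c(2L, 1L, 1L))
})

test_that("common-FOV cropping keeps every nonzero voxel of every map", {
  dm <- c(8L, 8L, 8L)
  mk <- function(v) structure(list(values = v, voxel_size_mm = 2, scaled = FALSE,
                                   code_table = c(background = 0, csf = 1, gm = 2,
                                                  wm = 3, lesion = 4)),
                              class = "ordinal_map")
  a <- array(0, dm); a[2:5, 2:5, 2:5] <- 2
  cr <- crop_common_fov(list(mk(a)))
  expect_equal(unname(cr$bbox), matrix(c(2, 5, 2, 5, 2, 5), 2))
  b <- array(0, dm); b[8, 8, 8] <- 1
  cr2 <- crop_common_fov(list(mk(a), mk(b)))
  expect_equal(unname(cr2$bbox[2, ]), c(8, 8, 8))
  expect_equal(sum(cr2$maps[[1]]$values != 0), sum(a != 0))
  expect_equal(sum(cr2$maps[[2]]$values != 0), sum(b != 0))
  expect_error(crop_common_fov(list(mk(array(0, dm)))), "all-zero")
})

test_that("scaling maps codes linearly onto [-1, 1] exactly once", {
  masks <- make_masks()
  m <- compose_ordinal_map(masks, array(FALSE, c(8L, 8L, 8L)))
  s <- scale_to_range(m)
  expect_equal(sort(unique(as.vector(s$values))), c(-0.5, 0, 0.5))
  m$values[1] <- 0; m$values[2] <- 4
  s2 <- scale_to_range(m)
  expect_equal(s2$values[1], -1)
  expect_equal(s2$values[2], 1)
  expect_equal(s2$values[3], 0)      # GM code 2 -> 0; order preserved
  expect_error(scale_to_range(s2), "already")
})

test_that("modal pooling preserves blob volume within the distortion bound", {
  # interior spherical blobs spanning several pooling blocks per axis
  # (>= ~2000 voxels at 4x pooling): 8 mm volume within +/- 20% of
  # (2 mm volume) / 64. Smaller blobs resonate with the block grid and can
  # deviate far more, whatever the pooling rule.
  dm <- c(48L, 48L, 48L)
  coords <- expand.grid(1:48, 1:48, 1:48)
  for (off in c(0, 0.5, 1.3)) {
    ctr <- c(24.5, 24.5, 24.5) + off
    d2 <- (coords[[1]] - ctr[1])^2 + (coords[[2]] - ctr[2])^2 +
      (coords[[3]] - ctr[3])^2
    for (r in c(8, 9.5, 11)) {
      lesion <- array(d2 <= r^2, dm)
      expect_gte(sum(lesion), 2000)
      masks <- list(csf = array(FALSE, dm), gm = array(!lesion, dm),
                    wm = array(FALSE, dm))
      m <- downsample_mode(compose_ordinal_map(masks, lesion), 4)
      ratio <- sum(m$values == 4) / (sum(lesion) / 64)
      expect_gte(ratio, 0.8)
      expect_lte(ratio, 1.2)
    }
  }
})

test_that("cohort lesion volumes remain commensurate after preprocessing", {
  # cortical lesions additionally lose surface blocks to background, so the
  # bound here is a looser sanity check than the interior-blob bound above
  co <- tiny_cohort()
  prep <- tiny_prep()
  vol2 <- co$truth$lesion_volume_voxels
  vol8 <- vapply(prep$maps, function(m) sum(m$values == 1), numeric(1))
  big <- which(vol2 >= 500)
  ratio <- vol8[big] / (vol2[big] / 64)
  expect_true(all(ratio >= 0.4 & ratio <= 1.3))
  expect_gt(cor(vol8[big], vol2[big]), 0.8)
})

test_that("NIfTI round trip is bit exact", {
  v <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  path <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, 8, path)
  back <- read_volume_nifti(path)
  expect_identical(back$values, v)
  expect_equal(back$voxel_size_mm, 8)
})
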
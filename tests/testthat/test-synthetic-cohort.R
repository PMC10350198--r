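test_that("template anatomy is symmetric, layered and deterministic", {
  tm <- tiny_template()
  expect_identical(tm$brain, tm$brain[dim(tm$brain)[1]:1, , ])
  expect_identical(tm$brain, build_anatomy_template(c(24L, 28L, 24L), 2)$brain)
  # hemispheres partition the brain
  expect_false(any(tm$left & tm$right))
  expect_identical(tm$left | tm$right, tm$brain)
  # tissue layers disjoint and nonempty
  expect_false(any(tm$csf & tm$gm) || any(tm$gm & tm$wm) || any(tm$csf & tm$wm))
  expect_true(all(sapply(tm[c("csf", "gm", "wm")], sum) > 0))
  expect_error(build_anatomy_template(c(8L, 8L, 8L)), "axis")
  expect_error(build_anatomy_template(c(17L, 20L, 20L)), "even")
})

test_that("lesion growth is confined, monotone and floors at one voxel", {
  tm <- tiny_template()
  l0 <- sample_lesion_mask(tm, 0, seed = 3)
  expect_identical(sum(l0), 1L)
  l2 <- sample_lesion_mask(tm, 0.2, seed = 3)
  l8 <- sample_lesion_mask(tm, 0.8, seed = 3)
  expect_lte(sum(l2), sum(l8))
  # prefix growth: the smaller lesion is nested in the larger one
  expect_true(all(l8[l2]))
  expect_true(all(!(l8 & !tm$left)))
})

test_that("atrophy conversion follows the burden-scaled pattern probability", {
  tm <- tiny_template()
  masks <- tm[c("csf", "gm", "wm")]
  # zero burden leaves tissue unchanged
  out0 <- apply_subtype_atrophy(masks, array(1, dim(tm$gm)), 0, seed = 1)
  expect_identical(out0$gm, masks$gm)
  expect_identical(out0$n_converted, 0L)
  # degenerate probability 1 over a known GM region converts it entirely
  gm_idx <- which(masks$gm)[1:100]
  pat <- array(0, dim(tm$gm)); pat[gm_idx] <- 1
  out1 <- apply_subtype_atrophy(masks, pat, 1, seed = 1)
  expect_identical(out1$n_converted, 100L)
  expect_true(all(out1$csf[gm_idx]))
  # stochastic counts stay within 3 binomial sigmas of the expectation
  pat2 <- array(0, dim(tm$gm)); pat2[which(masks$gm)[1:400]] <- 0.5
  counts <- vapply(1:5, function(s)
    apply_subtype_atrophy(masks, pat2, 1, seed = s)$n_converted, integer(1))
  expect_true(all(abs(counts - 200) <= 3 * sqrt(400 * 0.25)))
  expect_error(apply_subtype_atrophy(masks, array(1, c(2, 2, 2)), 1), "shape")
})

test_that("generated cohorts satisfy their structural invariants", {
  co <- tiny_cohort()
  tm <- co$template
  for (s in co$subjects) {
    expect_false(any(s$tissue_masks$csf & s$tissue_masks$gm))
    expect_false(any(s$tissue_masks$gm & s$tissue_masks$wm))
    expect_false(any(s$tissue_masks$csf & s$tissue_masks$wm))
    expect_true(all(!(s$lesion_mask & !tm$left)))
    expect_true(s$wab_aq >= 0 && s$wab_aq <= 100)
  }
  expect_equal(nrow(co$truth), 60)
})

test_that("severe prevalence is calibrated near the target", {
  co <- tiny_cohort()
  expect_lt(abs(mean(co$truth$wab_aq <= 50) - 0.35), 0.05 + 1e-9)
  fr <- vapply(21:25, function(s)
    mean(generate_cohort(cohort_spec(n_subjects = 60L,
                                     grid_shape = c(24L, 28L, 24L),
                                     seed = s))$truth$wab_aq <= 50), numeric(1))
  expect_true(all(abs(fr - 0.35) <= 0.05 + 1e-9))
})

test_that("severity decreases with planted burden when noise is removed", {
  co <- generate_cohort(cohort_spec(n_subjects = 30L, grid_shape = c(24L, 28L, 24L),
                                    noise_sd = 0, lesion_effect = 0, seed = 4L))
  ord <- order(co$truth$atrophy_burden)
  expect_true(all(diff(co$truth$wab_aq[ord]) <= 1e-9))
})

test_that("subtype assignment is independent of lesion size", {
  ps <- vapply(31:40, function(s) {
    tr <- generate_cohort(cohort_spec(n_subjects = 60L,
                                      grid_shape = c(24L, 28L, 24L),
                                      seed = s))$truth
    summary(stats::aov(lesion_volume_voxels ~ factor(true_subtype), tr))[[1]][1, 5]
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("cohorts round-trip to NIfTI volumes and a behavioral table", {
  co <- generate_cohort(cohort_spec(n_subjects = 12L, grid_shape = c(16L, 16L, 16L),
                                    seed = 2L))
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  tab <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(tab), 12)
  v <- read_volume_nifti(file.path(dir, "sub-0001_gm.nii.gz"))
  expect_equal(v$voxel_size_mm, 2)
  expect_identical(array(v$values > 0, dim(v$values)), co$subjects[[1]]$tissue_masks$gm)
})
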
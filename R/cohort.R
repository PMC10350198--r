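#' Specify a synthetic aphasia cohort
#'
#' Bundles and validates the generator parameters. Defaults emulate the
#' statistical structure the downstream analysis assumes: a cohort of 231
#' left-hemisphere stroke survivors, roughly 35% of whom fall at or below the
#' severe WAB-AQ cutoff of 50, with K planted multi-focal atrophy patterns
#' whose burden contributes to severity independently of lesion size.
#'
#' @param n_subjects cohort size (>= 12)
#' @param grid_shape 3 even voxel counts for the common template grid
#' @param voxel_size_mm isotropic voxel size of the generated volumes (mm)
#' @param severe_prevalence_target fraction of the cohort intended at or
#'   below WAB-AQ 50
#' @param n_subtypes number of planted atrophy patterns (>= 1)
#' @param atrophy_effect severity points lost per unit atrophy burden
#' @param lesion_effect severity points lost per lesion voxel
#' @param noise_sd residual severity noise, in WAB-AQ points
#' @param ceiling_const WAB-AQ of an unimpaired subject (near-maximum)
#' @param seed master seed; all randomness flows from it via named substreams
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 231L,
                        grid_shape = c(48L, 56L, 48L),
                        voxel_size_mm = 2,
                        severe_prevalence_target = 0.35,
                        n_subtypes = 4L,
                        atrophy_effect = 40,
                        lesion_effect = 0.005,
                        noise_sd = 8,
                        ceiling_const = 97.5,
                        seed = 1L) {
  if (n_subjects < 12) stop_input("n_subjects must be >= 12")
  if (severe_prevalence_target <= 0 || severe_prevalence_target >= 1)
    stop_input("severe_prevalence_target must be strictly inside (0, 1)")
  if (n_subtypes < 1) stop_input("n_subtypes must be >= 1")
  if (any(as.integer(grid_shape) %% 2 != 0)) stop_input("grid dimensions must be even")
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 severe_prevalence_target = severe_prevalence_target,
                 n_subtypes = as.integer(n_subtypes),
                 atrophy_effect = atrophy_effect,
                 lesion_effect = lesion_effect,
                 noise_sd = noise_sd,
                 ceiling_const = ceiling_const,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Calibrate a common multiplier on the structural effects so that the realized
# severe fraction (WAB-AQ <= 50) lands within +/- tol of the target. The
# fraction is nondecreasing in the multiplier, so a monotone grid/bisection
# search over a bounded range either succeeds or reports the achievable range.
calibrate_effect_scale <- function(base_deficit, noise, ceiling_const, target,
                                   tol = 0.05, cutoff = 50) {
  frac_at <- function(s) mean(pmin(100, pmax(0, ceiling_const - s * base_deficit + noise)) <= cutoff)
  s_grid <- exp(seq(log(1e-3), log(1e3), length.out = 400))
  fr <- vapply(s_grid, frac_at, numeric(1))
  best <- which.min(abs(fr - target))
  if (abs(fr[best] - target) > tol)
    stop_input("prevalence calibration failed: achievable severe fraction range is [%.3f, %.3f], target %.3f",
               min(fr), max(fr), target)
  s_grid[best]
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds the shared template, plants `n_subtypes` atrophy patterns, and for
#' each subject draws a lesion-size quantile, a subtype assignment and an
#' atrophy burden independently of each other (so subtype is not predictable
#' from lesion size). Severity follows a linear model with Gaussian noise,
#' clipped to [0, 100]:
#' `wab_aq = ceiling - s*(lesion_effect*volume + atrophy_effect*burden) + noise`,
#' where the common scale `s` is auto-calibrated so the realized fraction with
#' `wab_aq <= 50` is within 5 percentage points of the target prevalence.
#'
#' @param spec a [cohort_spec()]
#' @return list with `subjects` (each holding `subject_id`, `tissue_masks`,
#'   `lesion_mask`, `true_subtype`, `atrophy_burden`, `wab_aq`), a ground
#'   truth data frame `truth`, the `template`, the planted `patterns`, the
#'   calibrated `effect_scale` and the `spec`
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  template <- build_anatomy_template(spec$grid_shape, spec$voxel_size_mm, spec$seed)
  patterns <- make_subtype_patterns(template, spec$n_subtypes, spec$seed)
  n <- spec$n_subjects

  draws <- with_seed(substream_seed(spec$seed, "cohort"), list(
    size_q = stats::runif(n),
    # shuffled round-robin: subtypes appear in near-equal proportions while
    # remaining independent of lesion size and burden
    subtype = sample(rep_len(seq_len(spec$n_subtypes), n)),
    burden = stats::rgamma(n, shape = 3, scale = 0.4),
    noise = stats::rnorm(n, 0, spec$noise_sd)
  ))

  tissue <- list(csf = template$csf, gm = template$gm, wm = template$wm)
  subjects <- vector("list", n)
  lesion_vol <- integer(n)
  for (i in seq_len(n)) {
    lesion <- sample_lesion_mask(template, draws$size_q[i],
                                 seed = substream_seed(spec$seed, "lesion", i))
    atro <- apply_subtype_atrophy(tissue, patterns[[draws$subtype[i]]],
                                  draws$burden[i],
                                  seed = substream_seed(spec$seed, "atrophy", i))
    lesion_vol[i] <- sum(lesion)
    subjects[[i]] <- list(subject_id = sprintf("sub-%04d", i),
                          tissue_masks = list(csf = atro$csf, gm = atro$gm, wm = atro$wm),
                          lesion_mask = lesion,
                          true_subtype = draws$subtype[i],
                          atrophy_burden = draws$burden[i],
                          wab_aq = NA_real_)
  }

  base_deficit <- spec$lesion_effect * lesion_vol + spec$atrophy_effect * draws$burden
  s <- calibrate_effect_scale(base_deficit, draws$noise, spec$ceiling_const,
                              spec$severe_prevalence_target)
  wab <- pmin(100, pmax(0, spec$ceiling_const - s * base_deficit + draws$noise))
  for (i in seq_len(n)) subjects[[i]]$wab_aq <- wab[i]

  truth <- data.frame(subject_id = vapply(subjects, `[[`, "", "subject_id"),
                      wab_aq = wab,
                      true_subtype = draws$subtype,
                      atrophy_burden = draws$burden,
                      lesion_volume_voxels = lesion_vol,
                      stringsAsFactors = FALSE)
  list(subjects = subjects, truth = truth, template = template,
       patterns = patterns, effect_scale = s, spec = spec)
}

#' Write a cohort to disk as NIfTI volumes plus a behavioral table
#'
#' @param cohort output of [generate_cohort()]
#' @param dir output directory (created if missing)
#' @return invisibly, the path to `cohort.csv`
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vx <- cohort$spec$voxel_size_mm
  for (s in cohort$subjects) {
    for (tt in c("csf", "gm", "wm")) {
      write_volume_nifti(s$tissue_masks[[tt]] * 1L, vx,
                         file.path(dir, sprintf("%s_%s.nii.gz", s$subject_id, tt)))
    }
    write_volume_nifti(s$lesion_mask * 1L, vx,
                       file.path(dir, sprintf("%s_lesion.nii.gz", s$subject_id)))
  }
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(cohort$truth, csv, row.names = FALSE)
  invisible(csv)
}
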
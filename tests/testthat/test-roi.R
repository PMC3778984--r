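test_that("ROI mean is exact on uniform and single-voxel cases and checks inputs", {
  v <- array(0.5, c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4)); m[2, 3, 1] <- TRUE
  expect_equal(roi_mean(v, m), 0.5)
  v[2, 3, 1] <- 0.91
  expect_equal(roi_mean(v, m), 0.91)
  expect_equal(roi_mean(v, array(TRUE, c(4, 4, 4))),
               mean(v))
  # bounded by the volume's range
  expect_gte(roi_mean(v, m), min(v)); expect_lte(roi_mean(v, m), max(v))
  expect_error(roi_mean(v, array(FALSE, c(4, 4, 4))), "empty")
  expect_error(roi_mean(v, array(TRUE, c(4, 4, 5))), "4x4x4 vs 4x4x5")
  expect_error(roi_mean(v, array(2, c(4, 4, 4))), "binary")
})

test_that("FA asymmetry matches its closed forms, antisymmetry, and bounds", {
  expect_equal(fa_asymmetry(0.54, 0.42), 0.125)
  expect_equal(fa_asymmetry(0.37, 0.37), 0)
  expect_equal(fa_asymmetry(0.5, 0), 1)
  expect_error(fa_asymmetry(0, 0), "positive sum")
  withr::with_seed(11, {
    u <- runif(200); a <- runif(200)
    vals <- fa_asymmetry(u, a)
    expect_true(all(vals >= -1 & vals <= 1))
    expect_equal(fa_asymmetry(a, u), -vals)
  })
})

test_that("mask volume is voxel count times voxel volume", {
  m <- array(FALSE, c(5, 5, 5)); m[1:2, 1:4, 1:5] <- TRUE  # 40 voxels
  expect_equal(mask_volume_mm3(m, c(2, 2, 2)), 320)
  expect_equal(mask_volume_mm3(array(FALSE, c(3, 3, 3)), c(2, 2, 2)), 0)
  one <- array(FALSE, c(3, 3, 3)); one[1, 1, 1] <- TRUE
  expect_equal(mask_volume_mm3(one, c(1, 1, 1)), 1)
  expect_error(mask_volume_mm3(one, c(1, 1)), "three positive")
})

test_that("lesion-CST overlap counts thresholded intersection voxels", {
  sh <- c(10, 10, 4)
  lesion <- array(FALSE, sh); lesion[1:5, 1:2, 1] <- TRUE      # 10 voxels
  cst <- array(0, sh)
  # disjoint -> 0
  cst[6:10, 6:10, ] <- 1
  expect_equal(lesion_cst_overlap(lesion, cst, c(2, 2, 2)), 0)
  # constructed 10-voxel intersection at 2 mm isotropic -> 80 mm^3
  cst2 <- array(0, sh); cst2[1:5, 1:2, 1] <- 0.9; cst2[1, 1, 2] <- 1
  expect_equal(lesion_cst_overlap(lesion, cst2, c(2, 2, 2)), 80)
  # lesion contained in the thresholded map -> full lesion volume
  cst3 <- array(1, sh)
  expect_equal(lesion_cst_overlap(lesion, cst3, c(2, 2, 2)),
               mask_volume_mm3(lesion, c(2, 2, 2)))
  expect_error(lesion_cst_overlap(lesion, array(0.5, c(9, 10, 4)), c(2, 2, 2)),
               "grid mismatch")
  expect_error(lesion_cst_overlap(lesion, cst3, c(2, 2, 2), prob_threshold = 2),
               "\\[0, 1\\]")
})

test_that("overlap is monotone non-increasing in the probability threshold", {
  cfg <- gen_config(n_subjects = 3, seed = 41)
  st <- generate_cohort(cfg)[2, ]
  v <- generate_fa_volume(st, cfg)
  thr <- seq(0, 1, by = 0.1)
  ov <- vapply(thr, function(p) {
    lesion_cst_overlap(v$masks$lesion, v$cst, v$voxel_dims, p)
  }, numeric(1))
  expect_true(all(diff(ov) <= 0))
  expect_lte(max(ov), mask_volume_mm3(v$masks$lesion, v$voxel_dims))
})

test_that("noiseless phantoms return the configured hemisphere FA exactly", {
  cfg <- gen_config(n_subjects = 3, seed = 19, fa_noise_sd = 0)
  st <- generate_cohort(cfg)[1, ]
  v <- generate_fa_volume(st, cfg)
  expect_equal(roi_mean(v$fa, v$masks$plic_lesioned), st$fa_lesioned_true)
  expect_equal(roi_mean(v$fa, v$masks$plic_contralesional), st$fa_intact_true)
  s <- roi_stats(v)
  expect_equal(s$fa_asymmetry_plic,
               fa_asymmetry(st$fa_intact_true, st$fa_lesioned_true))
  expect_equal(s$fa_asymmetry_alic, 0)
  # ROI masks pairwise disjoint on the shared grid
  ms <- v$masks
  expect_equal(sum(ms$plic_lesioned & ms$plic_contralesional), 0)
  expect_equal(sum(ms$plic_lesioned & ms$alic_lesioned), 0)
  # too-small grids are refused
  expect_error(generate_fa_volume(st, gen_config(volume_shape = c(6, 6, 4))),
               "disjointly")
})

test_that("NIfTI round trip preserves data and voxel dimensions", {
  cfg <- gen_config(n_subjects = 3, seed = 29)
  v <- generate_fa_volume(generate_cohort(cfg)[1, ], cfg)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  nifti_write(v$fa, v$voxel_dims, path)
  back <- nifti_read(path)
  expect_equal(back$data, v$fa, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$voxel_dims, v$voxel_dims)
  # whole-set writer emits one file per volume
  dir <- withr::local_tempdir()
  paths <- write_volumes(v, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(sum(nifti_read(paths[["lesion"]])$data),
               sum(v$masks$lesion))
})

test_that("ALIC asymmetry is a severity-independent null while PLIC tracks severity", {
  rhos <- purrr::map_dfr(1:12, function(s) {
    cfg <- gen_config(n_subjects = 50, seed = 1000 + s)
    truth <- generate_cohort(cfg)
    stats <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      roi_stats(generate_fa_volume(truth[i, ], cfg))
    })
    tibble::tibble(
      alic = spearman_test(stats$fa_asymmetry_alic, truth$severity)$value,
      plic = spearman_test(stats$fa_asymmetry_plic, truth$severity)$value
    )
  })
  expect_gte(mean(abs(rhos$alic) < 0.3), 0.9)
  expect_lt(abs(mean(rhos$alic)), 0.12)
  expect_true(all(rhos$plic > 0.5))
})
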
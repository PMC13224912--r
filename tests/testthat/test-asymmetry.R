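test_that("FWHM/sigma conversion follows the Gaussian closed form", {
  expect_equal(fwhm_to_sigma(0, 2), c(0, 0, 0))
  expect_equal(fwhm_to_sigma(2 * sqrt(2 * log(2)), 1), rep(1, 3))
  expect_equal(fwhm_to_sigma(8, 2), rep(8 / (2 * sqrt(2 * log(2))) / 2, 3),
               tolerance = 1e-12)
})

test_that("effective resolution combines in quadrature", {
  r <- effective_resolution(c(6.6, 6.6, 5.1), 8)
  expect_equal(round(r[1], 1), 10.4)
  expect_equal(round(r[3], 1), 9.5)
  expect_equal(effective_resolution(c(6.6, 6.6, 5.1), 0), c(6.6, 6.6, 5.1))
})

test_that("mirror flipping is an involution mapping +x to -x", {
  set.seed(2)
  arr <- array(rnorm(24 * 20 * 16), c(24, 20, 16))
  img <- static_image(arr, 2)
  expect_equal(mirror_flip(mirror_flip(img))$voxels, arr)
  # a point source at +x appears at the mirrored -x position
  pt <- array(0, c(24, 20, 16)); pt[18, 5, 5] <- 1
  expect_equal(unname(which(mirror_flip(pt) == 1, arr.ind = TRUE)[1, 1]),
               24 + 1 - 18)
})

test_that("a symmetric image yields an identically zero asymmetry map", {
  up <- stats::setNames(rep(4, nrow(small_atlas$regions)),
                        small_atlas$regions$label)
  img <- render_static_fdg(small_atlas, up, psf_fwhm_mm = c(6.6, 6.6, 5.1),
                           noise_scale = 0)
  for (fw in c(0, 8)) {
    map <- percent_difference_map(img, small_atlas, "right", fw)
    expect_true(all(abs(map$delta_pct[map$mask]) < 1e-9))
  }
})

test_that("lesion contrast appears as the constructed percent difference", {
  up <- stats::setNames(rep(4, nrow(small_atlas$regions)),
                        small_atlas$regions$label)
  les <- lesion_spec("temporal_lobe", "left", 12, severity_frac = 0.2)
  img <- render_static_fdg(small_atlas, up, lesion = les, psf_fwhm_mm = 0,
                           noise_scale = 0)
  map <- percent_difference_map(img, small_atlas, "left", 0)
  core <- lesion_voxels(small_atlas, les) & map$mask
  expect_equal(mean(map$delta_pct[core]), -20, tolerance = 1e-9)
  # side swap: contralateral denominator gives +25 on the healthy side
  # (100 * (1 - 0.8) / 0.8); the symmetric denominator negates exactly
  map_r <- percent_difference_map(img, small_atlas, "right", 0)
  core_r <- mirror_flip(core) & map_r$mask
  expect_equal(mean(map_r$delta_pct[core_r]), 100 * 0.2 / 0.8,
               tolerance = 1e-9)
  map_s <- percent_difference_map(img, small_atlas, "left", 0,
                                  denominator = "symmetric")
  map_sr <- percent_difference_map(img, small_atlas, "right", 0,
                                   denominator = "symmetric")
  expect_equal(mean(map_s$delta_pct[core]),
               -mean(map_sr$delta_pct[mirror_flip(core)]),
               tolerance = 1e-9)
})

test_that("the suprathreshold mask retains the most affected fraction", {
  d <- array(NA_real_, c(10, 10, 2))
  msk <- array(FALSE, c(10, 10, 2)); msk[, , 1] <- TRUE
  d[, , 1] <- 0
  d[1:100] <- -seq(8.01, by = 0.2, length.out = 100)  # 100 suprathreshold
  map <- structure(list(delta_pct = d, mask = msk,
                        smoothing_fwhm_mm = 0, side = "left",
                        voxel_size_mm = c(2, 2, 2), denominator =
                          "contralateral", n_excluded = 0L),
                   class = "asymmetry_map")
  out <- lesion_mask(map, 8, 0.90)
  expect_equal(sum(out), 90)
  # the weakest 10 suprathreshold voxels are the ones dropped
  expect_true(all(d[out] <= -10.01))
  expect_equal(sum(lesion_mask(map, 30, 0.9)), 0)
})

test_that("lesion metrics are mean severity and voxel volume", {
  d <- array(NA_real_, c(10, 10, 10))
  d[1:1000] <- -20
  map <- structure(list(delta_pct = d, mask = !is.na(d),
                        smoothing_fwhm_mm = 0, side = "left",
                        voxel_size_mm = c(2, 2, 2), denominator =
                          "contralateral", n_excluded = 0L),
                   class = "asymmetry_map")
  met <- lesion_metrics(map, map$mask)
  expect_equal(met$severity_pct, -20)
  expect_equal(met$volume_mL, 1000 * 8 / 1000)
  empty <- lesion_metrics(map, array(FALSE, dim(d)))
  expect_true(is.na(empty$severity_pct))
  expect_equal(empty$volume_mL, 0)
})

test_that("smoothing monotonically suppresses background asymmetry noise", {
  up <- stats::setNames(rep(4, nrow(small_atlas$regions)),
                        small_atlas$regions$label)
  les <- lesion_spec("temporal_lobe", "left", 20, severity_frac = 0.3)
  img <- render_static_fdg(small_atlas, up, lesion = les,
                           psf_fwhm_mm = c(6.6, 6.6, 5.1),
                           noise_scale = 2, seed = 77)
  sweep <- kernel_sweep(img, small_atlas, "left",
                        kernels_mm = c(0, 4, 8, 12, 16, 20))
  expect_true(all(diff(sweep$background_noise_pct) < 0))
  # a noise-free symmetric input has exactly zero background at every kernel
  sym <- render_static_fdg(small_atlas, up, lesion = NULL,
                           psf_fwhm_mm = c(6.6, 6.6, 5.1), noise_scale = 0)
  sweep_sym <- kernel_sweep(sym, small_atlas, "left",
                            kernels_mm = c(0, 8, 16))
  expect_true(all(sweep_sym$background_noise_pct < 1e-9))
  img0 <- render_static_fdg(small_atlas, up, lesion = les,
                            psf_fwhm_mm = c(6.6, 6.6, 5.1), noise_scale = 0)
  sweep0 <- kernel_sweep(img0, small_atlas, "left",
                         kernels_mm = c(0, 8, 16))
  # a large lesion survives the 8-mm filter with only minor volume loss
  expect_gt(sweep0$lesion_volume_mL[sweep0$fwhm_mm == 8],
            0.8 * sweep0$lesion_volume_mL[sweep0$fwhm_mm == 0])
})

test_that("lesion severity is recovered from the asymmetry map core", {
  # one rendered subject with a known 30% synaptic-core severity: the mean
  # delta over the eroded true core recovers the injected severity
  cfg <- cohort_config(n_unblocked = 1, n_blocked = 0,
                       grid_shape = c(48, 48, 40), voxel_size_mm = 4,
                       lesion = list(center_region = "temporal_lobe",
                                     radius_late_mm = 20,
                                     radius_late_sd_mm = 0,
                                     radius_early_mm = 24,
                                     radius_early_sd_mm = 0,
                                     severity_mean = 0.30, severity_sd = 0,
                                     perfusion_mean = 0.05,
                                     perfusion_sd = 0,
                                     fdg_severity_mean = 0.25,
                                     fdg_severity_sd = 0,
                                     p_left = 1))
  coh <- generate_cohort(cfg, seed = 12, render = "images")
  s <- coh$subjects[[1]]
  late <- window_average(s$dynamic, 1800, 3600)
  map <- percent_difference_map(late, coh$atlas, "left", 0)
  core <- lesion_voxels(coh$atlas,
                        lesion_spec("temporal_lobe", "left", 10, 0.3))
  sel <- core & map$mask
  expect_equal(mean(map$delta_pct[sel]), -30, tolerance = 0.12)
})
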
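# two-region midline phantom used for rendering checks
render_atlas <- local({
  sp <- phantom_spec(c(24, 24, 20), 4, list(
    list(kind = "sphere", name = "core", tissue = "cortex",
         side = "midline", center_mm = c(0, 0, 0), radius_mm = 30),
    list(kind = "sphere", name = "pons", tissue = "pons",
         side = "midline", center_mm = c(0, 0, -36), radius_mm = 8)))
  build_phantom(sp)
})

render_sched <- parse_frame_spec("1x5,1x600")

test_that("noise-free, PSF-free rendering paints exact TAC values", {
  tacs <- list("1" = c(4, 2), "2" = c(1, 0.5))
  dyn <- render_dynamic_image(render_atlas, tacs, render_sched,
                              psf_fwhm_mm = 0, noise_scale = 0)
  expect_equal(unique(as.vector(dyn$voxels[, , , 1][render_atlas$labels == 1])), 4)
  expect_equal(unique(as.vector(dyn$voxels[, , , 2][render_atlas$labels == 2])), 0.5)
  expect_equal(unique(as.vector(dyn$voxels[, , , 1][render_atlas$labels == 0])), 0)
})

test_that("rendering is reproducible for a fixed seed", {
  tacs <- list("1" = c(4, 2), "2" = c(1, 0.5))
  a <- render_dynamic_image(render_atlas, tacs, render_sched,
                            noise_scale = 2, seed = 123)
  b <- render_dynamic_image(render_atlas, tacs, render_sched,
                            noise_scale = 2, seed = 123)
  expect_identical(a$voxels, b$voxels)
  c_ <- render_dynamic_image(render_atlas, tacs, render_sched,
                             noise_scale = 2, seed = 124)
  expect_false(identical(a$voxels, c_$voxels))
})

test_that("noise scales inversely with the square root of frame duration", {
  # equal activity in a 5-s and a 600-s frame; no PSF so the regions stay
  # uniform and the sample SD estimates the injected noise
  tacs <- list("1" = c(5, 5), "2" = c(5, 5))
  dyn <- render_dynamic_image(render_atlas, tacs, render_sched,
                              psf_fwhm_mm = 0, noise_scale = 2, seed = 5)
  core <- render_atlas$labels == 1
  sd_short <- sd(dyn$voxels[, , , 1][core])
  sd_long <- sd(dyn$voxels[, , , 2][core])
  expect_equal(sd_short / sd_long, sqrt(600 / 5), tolerance = 0.1)
})

test_that("a missing label TAC is reported by label", {
  expect_error(render_dynamic_image(render_atlas, list("1" = c(1, 1)),
                                    render_sched),
               "label\\(s\\) 2")
})

test_that("PSF blurring preserves interior regional means", {
  tacs <- list("1" = c(4, 2), "2" = c(1, 0.5))
  dyn <- render_dynamic_image(render_atlas, tacs, render_sched,
                              psf_fwhm_mm = c(6.6, 6.6, 5.1),
                              noise_scale = 0)
  # erode the 30-mm core to a 15-mm interior (2 x FWHM margin)
  gs <- dim(render_atlas$labels)
  co <- lapply(1:3, function(a)
    (seq_len(gs[a]) - (gs[a] + 1) / 2) * 4)
  R2 <- outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+")
  interior <- R2 <= 15^2
  expect_lt(abs(mean(dyn$voxels[, , , 1][interior]) / 4 - 1), 0.01)
})

test_that("a zero-severity static render is hemispherically symmetric", {
  up <- stats::setNames(rep(3, nrow(small_atlas$regions)),
                        small_atlas$regions$label)
  img <- render_static_fdg(small_atlas, up, lesion = NULL,
                           psf_fwhm_mm = c(6.6, 6.6, 5.1), noise_scale = 0)
  map <- percent_difference_map(img, small_atlas, "left", 0)
  expect_equal(mean(map$delta_pct[map$mask]), 0, tolerance = 1e-10)
})

test_that("a lesion scales the core by one minus severity before noise", {
  up <- stats::setNames(rep(3, nrow(small_atlas$regions)),
                        small_atlas$regions$label)
  les <- lesion_spec("temporal_lobe", "left", 10, severity_frac = 0.2)
  img <- render_static_fdg(small_atlas, up, lesion = les,
                           psf_fwhm_mm = 0, noise_scale = 0)
  core <- lesion_voxels(small_atlas, les)
  expect_equal(unique(as.vector(img$voxels[core])), 3 * 0.8)
  mirror_core <- mirror_flip(core)
  expect_equal(mean(img$voxels[core]) / mean(img$voxels[mirror_core]), 0.8)
})

test_that("lesion voxels stay within one hemisphere", {
  les <- lesion_spec("temporal_lobe", "right", 25, 0.3)
  vox <- lesion_voxels(small_atlas, les)
  idx <- which(vox, arr.ind = TRUE)
  expect_true(all(idx[, 1] > dim(small_atlas$labels)[1] / 2))
})
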
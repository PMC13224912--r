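make_dyn <- function(vals_by_frame, sched, vox = 4) {
  arr <- array(rep(vals_by_frame, each = 4 * 4 * 3), c(4, 4, 3,
                                                       length(vals_by_frame)))
  dynamic_image(arr, sched, vox, injected_dose_MBq = 185,
                body_weight_kg = 74)
}

test_that("SUV conversion follows dose-per-gram normalisation", {
  # 185 MBq / 74 kg = 2.5 kBq/g, so 2.5 kBq/mL maps to SUV 1
  expect_equal(suv(2.5, dose_MBq = 185, weight_kg = 74), 1.0)
  expect_equal(suv(0, dose_MBq = 185, weight_kg = 74), 0)
  expect_equal(suv(2.5, dose_MBq = 370, weight_kg = 74),
               0.5 * suv(2.5, dose_MBq = 185, weight_kg = 74))
  expect_error(suv(1, dose_MBq = -1, weight_kg = 70), "positive")
  expect_error(suv(1, dose_MBq = 100, weight_kg = 0), "positive")
})

test_that("window averaging is duration-weighted and conservative", {
  sched <- parse_frame_spec("2x60,1x120")
  dyn <- make_dyn(c(1, 3, 5), sched)
  # constant-valued voxels stay constant
  cdyn <- make_dyn(c(2, 2, 2), sched)
  expect_true(all(window_average(cdyn, 0, 240)$voxels == 2))
  # full scan equals the duration-weighted mean of all frames
  full <- window_average(dyn, 0, 240)
  expect_equal(unique(as.vector(full$voxels)),
               sum(c(1, 3, 5) * c(60, 60, 120)) / 240)
  # only fully contained frames participate
  expect_equal(unique(as.vector(window_average(dyn, 0, 130)$voxels)), 2)
  expect_error(window_average(dyn, 30, 50), "no frame")
})

test_that("the late window of the standard schedule uses the 3 x 600 s frames", {
  vals <- seq_len(35)
  dyn <- make_dyn(vals, paper_sched)
  expect_equal(unique(as.vector(window_average(dyn, 1800, 3600)$voxels)),
               mean(33:35))
})

test_that("SUVR normalises to the reference and is scale invariant", {
  set.seed(5)
  arr <- array(stats::runif(prod(dim(small_atlas$labels)), 1, 5),
               dim(small_atlas$labels))
  img <- static_image(arr, small_atlas$voxel_size_mm)
  out <- suvr(img, small_atlas, "cerebellum")
  ref_sel <- small_atlas$labels %in%
    small_atlas$regions$label[small_atlas$regions$tissue == "cerebellum"]
  expect_equal(mean(out$voxels[ref_sel]), 1)
  img2 <- img; img2$voxels <- img$voxels * 3.7
  expect_equal(suvr(img2, small_atlas, "cerebellum")$voxels, out$voxels)
  # different references only rescale: regional rank order is preserved
  out_pons <- suvr(img, small_atlas, "pons")
  reg_means <- function(x) vapply(small_atlas$regions$label, function(lb)
    mean(x$voxels[small_atlas$labels == lb]), numeric(1))
  expect_equal(cor(reg_means(out), reg_means(out_pons),
                   method = "spearman"), 1)
  # degenerate references error
  zero <- img; zero$voxels[] <- 0
  expect_error(suvr(zero, small_atlas, "pons"), "positive")
  expect_error(suvr(img, small_atlas, "no_such_region"))
})

test_that("NIfTI round-trips preserve values, voxel size and frame count", {
  set.seed(9)
  sched <- parse_frame_spec("3x60")
  arr <- array(stats::rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3))
  dyn <- dynamic_image(arr, sched, c(2, 2, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_pet_nifti(dyn, path)
  back <- read_dynamic_nifti(path, sched)
  expect_identical(dim(back$voxels), dim(arr))
  expect_equal(as.vector(back$voxels), as.vector(arr))
  expect_equal(back$voxel_size_mm, c(2, 2, 3))
  # a 3D file is rejected as dynamic and vice versa
  p3 <- tempfile(fileext = ".nii.gz")
  write_pet_nifti(static_image(arr[, , , 1], c(2, 2, 3)), p3)
  expect_error(read_dynamic_nifti(p3, sched), "4D")
  expect_error(read_static_nifti(path), "3D")
  st <- read_static_nifti(p3)
  expect_equal(st$voxels, arr[, , , 1], ignore_attr = TRUE)
  # label volumes round-trip with their region table
  pl <- tempfile(fileext = ".nii.gz")
  write_pet_nifti(small_atlas, pl)
  back_at <- read_label_nifti(pl, small_atlas$regions)
  expect_identical(back_at$labels, small_atlas$labels)
  unlink(c(path, p3, pl))
})
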
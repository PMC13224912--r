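test_that("Logan VT recovers K1/k2 on noise-free one-tissue curves", {
  tac <- simulate_tac(kinetic_params(0.2, 0.1), test_cp, paper_sched)
  fit <- logan_vt(tac, test_cp, t_star_min = 15)
  expect_equal(fit$VT, 2.0, tolerance = 0.02)
  expect_gt(fit$r2, 0.999)
  # VT is linear in K1
  tac2 <- simulate_tac(kinetic_params(0.4, 0.1), test_cp, paper_sched)
  expect_equal(logan_vt(tac2, test_cp, 15)$VT, 2 * fit$VT,
               tolerance = 1e-6)
  expect_error(logan_vt(tac, test_cp, t_star_min = 70), "at least 3")
})

test_that("Logan VT matches the closed form across kinetics and fit starts", {
  for (p in list(c(0.1, 0.02), c(0.15, 0.05), c(0.3, 0.15))) {
    tac <- simulate_tac(kinetic_params(p[1], p[2]), test_cp, paper_sched)
    for (ts in c(10, 15, 25)) {
      vt <- logan_vt(tac, test_cp, ts)$VT
      expect_lt(abs(vt / (p[1] / p[2]) - 1), 0.02)
    }
  }
})

test_that("reference Logan DVR equals the VT ratio on one-tissue data", {
  target <- simulate_tac(kinetic_params(0.2, 0.1), test_cp, paper_sched)
  refer <- simulate_tac(kinetic_params(0.1, 0.2), test_cp, paper_sched)
  d <- logan_dvr(target, refer, 15, k2_ref = 0.2)
  expect_equal(d$DVR, 4.0, tolerance = 0.03)
  # oracle equivalence: DVR vs ratio of independent Logan VT fits
  vt_t <- logan_vt(target, test_cp, 15)$VT
  vt_r <- logan_vt(refer, test_cp, 15)$VT
  expect_equal(d$DVR, vt_t / vt_r, tolerance = 0.03)
  # the region against itself has DVR 1
  self <- logan_dvr(target, target, 15, k2_ref = 0.1)
  expect_equal(self$DVR, 1, tolerance = 1e-6)
})

test_that("image-derived input functions recover the plasma curve", {
  # noise-free, PSF-free render: frame averages of Cp come back exactly
  sp <- phantom_spec(c(16, 16, 12), 4, list(
    list(kind = "sphere", name = "blood_pool", tissue = "blood",
         side = "midline", center_mm = c(0, 0, 0), radius_mm = 12)))
  at <- build_phantom(sp)
  cp_avg <- dualphasepet:::frame_average(test_cp$cp, test_cp$time_s, paper_sched)
  dyn <- render_dynamic_image(at, list("1" = cp_avg), paper_sched,
                              psf_fwhm_mm = 0, noise_scale = 0)
  idif <- idif_extract(dyn, at$labels == 1)
  got <- dualphasepet:::frame_average(idif$cp, idif$time_s, paper_sched)
  # linear interpolation between midpoints is the only distortion
  expect_equal(got, cp_avg, tolerance = 0.05)
  expect_error(idif_extract(dyn, at$labels == 99), "empty")
})

test_that("the rendered blood pool reproduces the bolus peak position", {
  s <- img_cohort$subjects[[1]]
  at <- img_cohort$atlas
  blood <- at$labels %in% at$regions$label[at$regions$tissue == "blood"]
  idif <- idif_extract(s$dynamic, blood)
  t_peak_idif <- idif$time_s[which.max(idif$cp)] / 60
  t_peak_true <- s$cp$time_s[which.max(s$cp$cp)] / 60
  # the PSF dilutes and delays the small blood pool: coarse agreement only
  expect_lt(abs(t_peak_idif - t_peak_true), 1.5)
  truth_frames <- dualphasepet:::frame_average(s$cp$cp, s$cp$time_s,
                                               img_cohort$schedule)
  idif_frames <- dualphasepet:::frame_average(idif$cp, idif$time_s,
                                              img_cohort$schedule)
  expect_gt(cor(truth_frames, idif_frames), 0.9)
})

test_that("static late-phase SUVR agrees with kinetic outcome measures", {
  agree <- static_vs_kinetic_agreement(tac_cohort)
  reg <- tac_cohort$atlas$regions
  ctx_labels <- as.character(reg$label[reg$tissue == "cortex"])
  ctx <- agree[agree$region %in% ctx_labels, ]
  expect_true(all(ctx$r_vtr > 0.9))
  expect_true(all(ctx$r_dvr > 0.9))
  expect_true(all(ctx$p_vtr < 0.01))
  # DVR tracks the VT ratio across all regions with specific binding (the
  # reference region itself is a near-constant ratio, so it is excluded)
  nonref <- as.character(reg$label[!reg$tissue %in%
                                     c("centrum_semiovale", "blood")])
  expect_gt(min(agree$r_dvr[agree$region %in% nonref]), 0.8)
})
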
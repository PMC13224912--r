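test_that("TAC extraction averages over the mask", {
  sched <- parse_frame_spec("2x30")
  arr <- array(1, c(6, 6, 4, 2))
  arr[1, 1, 1, ] <- c(7, 9)
  dyn <- dynamic_image(arr, sched, 4)
  expect_equal(extract_tac(dyn, array(TRUE, c(6, 6, 4)))$value,
               c(mean(arr[, , , 1]), mean(arr[, , , 2])))
  one <- array(FALSE, c(6, 6, 4)); one[1, 1, 1] <- TRUE
  expect_equal(extract_tac(dyn, one)$value, c(7, 9))
  expect_error(extract_tac(dyn, array(FALSE, c(6, 6, 4))), "empty")
})

test_that("peak location uses frame midpoints with earliest tie-breaking", {
  sched <- parse_frame_spec("4x60")
  dec <- data.frame(midpoint_s = sched$midpoint_s, value = c(4, 3, 2, 1))
  expect_equal(tac_peak(dec)$t_peak_min, 0.5)
  zero <- data.frame(midpoint_s = sched$midpoint_s, value = rep(0, 4))
  expect_equal(tac_peak(zero)$t_peak_min, 0.5)
  expect_equal(tac_peak(zero)$peak_value, 0)
  tie <- data.frame(midpoint_s = sched$midpoint_s, value = c(1, 5, 5, 1))
  expect_equal(tac_peak(tie)$t_peak_min, 1.5)
})

test_that("cohort cortical peaks match the configured kinetics", {
  reg <- tac_cohort$atlas$regions
  ctx <- as.character(reg$label[reg$tissue == "cortex"][1])
  tr <- tac_cohort$truth
  peaks <- vapply(tac_cohort$subjects, function(s)
    tac_peak(s$tacs[[ctx]])$t_peak_min, numeric(1))
  expect_equal(mean(peaks[!tr$blocked]), 4.0, tolerance = 0.6)
  expect_lt(mean(peaks[tr$blocked]), mean(peaks[!tr$blocked]))
})

test_that("identical groups give zero change and p = 1", {
  sched <- parse_frame_spec("2x300")
  vals <- c(3, 4)
  tab <- do.call(rbind, lapply(sprintf("s%d", 1:4), function(id)
    data.frame(subject = id, region = "cortex",
               frame = 1:2, frame_start_s = sched$start_s,
               frame_duration_s = sched$duration_s,
               midpoint_s = sched$midpoint_s,
               value = vals + (id %in% c("s2", "s4")))))
  blocked <- c(s1 = FALSE, s2 = FALSE, s3 = TRUE, s4 = TRUE)
  out <- compare_groups(tab, blocked, windows = list(full = c(0, 600)))
  expect_equal(out$percent_change, 0)
  expect_equal(out$raw_p, 1)
  expect_error(compare_groups(tab[tab$subject != "s4", ], blocked),
               "at least 2")
})

test_that("the blocked arm shows the late-but-not-early reduction pattern", {
  tt <- collapse_tissue(cohort_tac_table(tac_cohort), tac_cohort$atlas)
  blocked <- stats::setNames(tac_cohort$truth$blocked,
                             tac_cohort$truth$subject)
  cmp <- compare_groups(tt[tt$region != "blood", ], blocked)
  late <- cmp[cmp$window == "late", ]
  early <- cmp[cmp$window == "early", ]
  ctx_late <- late[late$region == "cortex", ]
  # pronounced, significant late-window cortical reduction
  expect_lt(ctx_late$percent_change, -35)
  expect_gt(ctx_late$percent_change, -70)
  expect_lt(ctx_late$adjusted_p, 0.05)
  # early window: no significant group difference anywhere
  expect_true(all(early$adjusted_p > 0.05))
  # the reference white matter is insensitive to blockade
  cso_late <- late[late$region == "centrum_semiovale", ]
  expect_lt(abs(cso_late$percent_change), 15)
  expect_gt(cso_late$adjusted_p, 0.05)
  # Holm-Sidak step-down never lowers a p value
  expect_true(all(cmp$adjusted_p >= cmp$raw_p - 1e-12))
})

test_that("late-window percent change tracks occupancy at low noise", {
  # parameter recovery: with occupancy o and near-total specific binding,
  # the late-window group change approaches -100 * o * specific_fraction
  cfg <- cohort_config(n_unblocked = 10, n_blocked = 10,
                       grid_shape = c(48, 48, 40), voxel_size_mm = 4,
                       noise_scale = 0)
  coh <- generate_cohort(cfg, seed = 31, render = "tac")
  tt <- collapse_tissue(cohort_tac_table(coh), coh$atlas)
  blocked <- stats::setNames(coh$truth$blocked, coh$truth$subject)
  cmp <- compare_groups(tt[tt$region == "cortex", ], blocked)
  occ <- mean(coh$truth$occupancy[coh$truth$blocked])
  late_pc <- cmp$percent_change[cmp$window == "late"]
  expect_equal(late_pc, -100 * occ, tolerance = 0.35)
  expect_lt(late_pc, 0)
})
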
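test_that("pearson_r_p matches the closed form and the reference test", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_r_p(x, 2 * x + 1)$r, 1)
  set.seed(3)
  a <- rnorm(15); b <- 0.5 * a + rnorm(15)
  mine <- pearson_r_p(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(mine$r, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value)
  expect_error(pearson_r_p(rep(1, 5), 1:5), "variance")
  expect_error(pearson_r_p(1:2, 2:1), "at least 3")
})

test_that("printed correlation p values are reproduced at n = 21", {
  expect_equal(round(pearson_p(0.70, 21), 4), 0.0004)
  expect_equal(round(pearson_p(0.14, 21), 2), 0.55)
})

test_that("the t-based p agrees with a permutation oracle", {
  set.seed(8)
  x <- rnorm(9)
  y <- 0.45 * x + rnorm(9)
  p_t <- pearson_r_p(x, y)$p
  p_perm <- permutation_pearson_p(x, y)
  # Monte-Carlo error at 20k permutations is ~ sqrt(p(1-p)/20000) < 0.004
  expect_lt(abs(p_t - p_perm), 0.03)
})

test_that("framewise correlation flags degenerate inputs", {
  sched <- parse_frame_spec("3x60")
  dv <- do.call(rbind, lapply(sprintf("s%d", 1:6), function(id)
    data.frame(subject = id, frame = 1:3, midpoint_s = sched$midpoint_s,
               value = rnorm(3, 10))))
  static <- stats::setNames(dv$value[dv$frame == 1],
                            unique(dv$subject))
  # the static value duplicated as every frame correlates perfectly
  dv1 <- dv
  dv1$value <- rep(static, each = 3)
  out <- framewise_correlation(dv1, static)
  expect_true(all(abs(out$r - 1) < 1e-12))
  expect_equal(out$n, rep(6, 3))
  # fewer than 3 complete subjects errors
  expect_error(framewise_correlation(dv[dv$subject %in% c("s1", "s2"), ],
                                     static), "fewer than 3")
  # subjects without the static modality are excluded and counted
  out2 <- framewise_correlation(dv1, static[1:5])
  expect_equal(attr(out2, "n_excluded"), 1)
  expect_equal(out2$n, rep(5, 3))
})

test_that("delivery-driven early frames correlate while independent-binding late frames do not", {
  # construct a cohort whose FDG signal is proportional to K1 while VT
  # varies independently: early frames should correlate, late frames not
  set.seed(21)
  n <- 20
  K1 <- rlnorm(n, log(0.15), 0.25)
  VT <- rlnorm(n, log(4.5), 0.25)
  rows <- list()
  fdg <- numeric(n)
  for (i in seq_len(n)) {
    tc <- simulate_tac(kinetic_params(K1[i], K1[i] / VT[i]), test_cp,
                       paper_sched)
    rows[[i]] <- data.frame(subject = sprintf("s%02d", i),
                            frame = seq_len(35),
                            midpoint_s = paper_sched$midpoint_s,
                            value = tc$value)
    fdg[i] <- K1[i] * exp(rnorm(1, 0, 0.05))
  }
  dv <- do.call(rbind, rows)
  names(fdg) <- sprintf("s%02d", seq_len(n))
  cur <- framewise_correlation(dv, fdg)
  early <- cur$frame >= 5 & cur$midpoint_s <= 600
  late <- cur$midpoint_s >= 1800
  expect_true(all(cur$p[early] < 0.05))
  expect_true(all(cur$r[early] > 0.5))
  expect_lt(mean(abs(cur$r[late])), mean(cur$r[early]))
  expect_true(mean(cur$p[late] > 0.05) > 0.5)
})

test_that("within-subject regional agreement degrades late under blockade", {
  reg <- tac_cohort$atlas$regions
  use <- reg$tissue != "blood" & reg$side %in% c("right", "midline")
  regions <- reg$name[use]
  s <- tac_cohort$subjects[[which(tac_cohort$truth$blocked)[1]]]
  win_means <- function(t0, t1) {
    v <- vapply(as.character(reg$label[use]), function(lb)
      tac_window_mean(s$tacs[[lb]], t0, t1), numeric(1))
    stats::setNames(v, regions)
  }
  fdg <- stats::setNames(s$fdg_uptake[as.character(reg$label[use])], regions)
  early <- intrasubject_region_correlation(win_means(0, 600), fdg, regions)
  late <- intrasubject_region_correlation(win_means(1800, 3600), fdg, regions)
  expect_gt(early$r, late$r)
  expect_gt(early$r, 0.5)
  expect_lt(early$p, 0.05)
  # identity gives r = 1; tiny region sets error
  expect_equal(intrasubject_region_correlation(fdg, fdg, regions)$r, 1)
  expect_error(intrasubject_region_correlation(fdg, fdg, regions[1:2]),
               "at least 3")
})

test_that("window selection returns maximal significant runs as intervals", {
  p <- rep(0.5, 35)
  cur <- data.frame(frame = 1:35, midpoint_s = paper_sched$midpoint_s,
                    r = 0.5, p = p)
  expect_equal(nrow(select_windows(cur, paper_sched)), 0)
  # significance confined to frames 11-27 maps to about 1-10 min
  p[11:27] <- 0.01
  cur$p <- p
  w <- select_windows(cur, paper_sched)
  expect_equal(nrow(w), 1)
  expect_equal(w$t_start_s, paper_sched$start_s[11])  # 50 s
  expect_equal(w$t_end_s, paper_sched$end_s[27])      # 540 s
  # a single significant frame qualifies only with min_run = 1
  p2 <- rep(0.5, 35); p2[4] <- 0.01
  cur$p <- p2
  expect_equal(nrow(select_windows(cur, paper_sched)), 0)
  w1 <- select_windows(cur, paper_sched, min_run = 1)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$t_start_s, w1$t_end_s - 5)
})
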
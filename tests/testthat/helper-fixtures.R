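# Shared fixtures: a desk-scale 4-mm phantom, the standard 35-frame
# schedule, a template input function, and two cached cohorts (regional
# curves for 21 + 8 subjects; rendered volumes for a small paired cohort).
# Everything is generated in code at load time.

paper_sched <- parse_frame_spec("12x5,6x10,3x20,7x60,4x300,3x600")
test_cp <- input_function(total_duration(paper_sched) + 1)

small_spec <- default_phantom_spec(c(48, 48, 40), 4, n_cortex_sectors = 10)
small_atlas <- build_phantom(small_spec)

small_cfg <- cohort_config(grid_shape = c(48, 48, 40), voxel_size_mm = 4)

# regional-curve cohort at the emulated study size (21 unblocked, 8 blocked)
tac_cohort <- generate_cohort(small_cfg, seed = 42, render = "tac")

# rendered paired cohort, 5 unblocked + 1 blocked
img_cfg <- cohort_config(n_unblocked = 5, n_blocked = 1,
                         grid_shape = c(48, 48, 40), voxel_size_mm = 4)
img_cohort <- generate_cohort(img_cfg, seed = 7, render = "images")

# brute-force oracle for the one-tissue convolution: trapezoidal Riemann
# sum of K1 * Cp(tau) * exp(-k2 (t - tau)) on a 0.1-s grid, averaged per
# frame
brute_force_tac <- function(K1, k2, cp, sched, dt_s = 0.1) {
  t_fine <- seq(0, sched$end_s[nrow(sched)], by = dt_s)
  cp_fine <- stats::approx(cp$time_s, cp$cp, xout = t_fine, rule = 2)$y
  dt_min <- dt_s / 60
  expk <- exp(-k2 * t_fine / 60)
  # ct(t_i) = K1 * sum_{j<=i} w_j cp(t_j) exp(-k2 (t_i - t_j)) dt with
  # trapezoid weights (1/2 at the interval ends)
  g <- cp_fine / expk
  s <- cumsum(g) - g / 2 - g[1] / 2
  ct <- K1 * expk * s * dt_min
  vapply(seq_len(nrow(sched)), function(i) {
    sel <- t_fine >= sched$start_s[i] & t_fine <= sched$end_s[i]
    mean(ct[sel])
  }, numeric(1))
}

# Monte-Carlo permutation p-value for a Pearson correlation
permutation_pearson_p <- function(x, y, n_perm = 20000, seed = 1) {
  set.seed(seed)
  r_obs <- abs(stats::cor(x, y))
  hits <- sum(vapply(seq_len(n_perm), function(i)
    abs(stats::cor(x, sample(y))) >= r_obs - 1e-12, logical(1)))
  (hits + 1) / (n_perm + 1)
}

# independent step-down reference for the Sidak adjustment
brute_force_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, a)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}
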
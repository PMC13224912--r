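#' Cohort generator configuration
#'
#' Defaults encode the emulated study conditions: 21 unblocked + 8 blocked
#' subjects; a 35-frame 60-min dynamic acquisition; per-arm cortical peak
#' distributions (unblocked SUV 7.4 +/- 1.6 peaking at 4.0 +/- 0.7 min;
#' blocked SUV 6.4 +/- 2.3 peaking at 2.7 +/- 0.8 min); injected activity
#' 185.1 +/- 13.6 MBq (dynamic tracer) and 146.7 +/- 10.5 MBq (FDG); an
#' intrinsic scanner resolution of 6.6 x 6.6 x 5.1 mm; and a unilateral
#' temporal lesion in every subject whose metabolic/perfusion extent is
#' broader than its synaptic (late-phase) core. Regional kinetic
#' multipliers relative to cortex and absolute FDG uptake values are free
#' parameters of the phantom (no regional table is available to emulate);
#' the centrum semiovale is modelled as 90% nondisplaceable signal, so it
#' is nearly insensitive to blockade.
#'
#' @param n_unblocked,n_blocked arm sizes.
#' @param frame_spec compact frame specification string
#'   (see [parse_frame_spec()]).
#' @param grid_shape,voxel_size_mm,n_cortex_sectors phantom grid (see
#'   [default_phantom_spec()]).
#' @param unblocked_peak,blocked_peak lists with `suv_mean`, `suv_sd`,
#'   `time_mean`, `time_sd` (SUV; minutes) for the cortical peak draws.
#' @param dose_MBq,fdg_dose_MBq lists with `mean`, `sd` (MBq).
#' @param weight_kg list with `mean`, `sd` (kg).
#' @param psf_fwhm_mm intrinsic resolution FWHM (mm).
#' @param noise_scale rendering noise amplitude (see
#'   [render_dynamic_image()]); 0 disables noise.
#' @param lesion list with `center_region`; `radius_late_mm`,
#'   `radius_late_sd_mm` (synaptic core extent: mean and per-subject SD);
#'   `radius_early_mm`, `radius_early_sd_mm` (perfusion/metabolic extent,
#'   one draw shared by the early dynamic phase and FDG, so their lesion
#'   volumes co-vary across subjects while the synaptic core varies
#'   independently); `severity_mean`, `severity_sd` (binding reduction);
#'   `perfusion_mean`, `perfusion_sd` (delivery reduction);
#'   `fdg_severity_mean`, `fdg_severity_sd`; and `p_left` (probability the
#'   lesion is left-sided).
#' @param regional data frame of per-tissue multipliers: `tissue`,
#'   `K1_mult`, `VT_mult`, `specific_frac`, `fdg_uptake`.
#' @param region_cv lognormal coefficient of variation of the per-subject,
#'   per-region delivery and binding multipliers (delivery is shared with
#'   FDG uptake; binding is independent).
#' @param cp_dt_s input-function sampling interval (s).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_unblocked = 21, n_blocked = 8,
                          frame_spec = "12x5,6x10,3x20,7x60,4x300,3x600",
                          grid_shape = c(96, 96, 80), voxel_size_mm = 2,
                          n_cortex_sectors = 10,
                          unblocked_peak = list(suv_mean = 7.4, suv_sd = 1.6,
                                                time_mean = 4.0, time_sd = 0.7),
                          blocked_peak = list(suv_mean = 6.4, suv_sd = 2.3,
                                              time_mean = 2.7, time_sd = 0.8),
                          dose_MBq = list(mean = 185.1, sd = 13.6),
                          fdg_dose_MBq = list(mean = 146.7, sd = 10.5),
                          weight_kg = list(mean = 75, sd = 12),
                          psf_fwhm_mm = c(6.6, 6.6, 5.1),
                          noise_scale = 2,
                          lesion = list(center_region = "temporal_lobe",
                                        radius_late_mm = 8,
                                        radius_late_sd_mm = 1.5,
                                        radius_early_mm = 14,
                                        radius_early_sd_mm = 2.5,
                                        severity_mean = 0.45, severity_sd = 0.06,
                                        perfusion_mean = 0.22, perfusion_sd = 0.05,
                                        fdg_severity_mean = 0.22,
                                        fdg_severity_sd = 0.05,
                                        p_left = 18 / 29),
                          regional = default_regional_table(),
                          region_cv = 0.08,
                          cp_dt_s = 0.5) {
  cfg <- list(n_unblocked = n_unblocked, n_blocked = n_blocked,
              frame_spec = frame_spec, grid_shape = grid_shape,
              voxel_size_mm = voxel_size_mm,
              n_cortex_sectors = n_cortex_sectors,
              unblocked_peak = unblocked_peak, blocked_peak = blocked_peak,
              dose_MBq = dose_MBq, fdg_dose_MBq = fdg_dose_MBq,
              weight_kg = weight_kg, psf_fwhm_mm = psf_fwhm_mm,
              noise_scale = noise_scale, lesion = lesion,
              regional = regional, region_cv = region_cv, cp_dt_s = cp_dt_s)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_regional_table <- function() {
  data.frame(
    tissue = c("cortex", "temporal_lobe", "basal_ganglia", "thalamus",
               "cerebellum", "centrum_semiovale", "pons", "blood"),
    K1_mult = c(1.00, 0.95, 1.05, 1.05, 1.00, 0.35, 0.75, NA),
    VT_mult = c(1.00, 0.95, 0.90, 0.80, 0.90, 0.40, 0.65, NA),
    specific_frac = c(1.00, 1.00, 0.95, 0.90, 0.95, 0.10, 0.60, NA),
    fdg_uptake = c(6.0, 5.7, 6.3, 6.0, 5.4, 1.8, 4.2, 1.5)
  )
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_unblocked >= 0, cfg$n_blocked >= 0,
            cfg$n_unblocked + cfg$n_blocked >= 1,
            cfg$noise_scale >= 0, cfg$region_cv >= 0,
            all(c("tissue", "K1_mult", "VT_mult", "specific_frac",
                  "fdg_uptake") %in% names(cfg$regional)))
  les <- cfg$lesion
  if (!is.null(les))
    stopifnot(les$radius_late_mm > 0,
              les$radius_early_mm >= les$radius_late_mm,
              les$severity_mean > 0, les$severity_mean < 1,
              les$p_left >= 0, les$p_left <= 1)
  invisible(cfg)
}

# normal draw truncated to [lo, hi] by redraw
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

# k2 (1/min) whose noise-free 1TC response to `cp` peaks at `peak_min`
solve_k2_for_peak <- function(peak_min, cp) {
  f <- function(k2) {
    ct <- ct_fine(1, k2, cp)
    cp$time_s[which.max(ct)] / 60 - peak_min
  }
  stats::uniroot(f, c(0.004, 3), tol = 1e-6)$root
}

#' Generate a synthetic paired dynamic/static cohort
#'
#' Draws per-subject parameters (arm-specific cortical peak SUV and peak
#' time, dose, weight, lesion severity and side, per-region delivery and
#' binding variability), calibrates one-tissue kinetics per subject by
#' inverting the noise-free peak, and simulates regional TACs for every
#' atlas label plus a matching static FDG pattern. Blocked subjects draw an
#' additional unblocked-style baseline peak time; their occupancy is the
#' value implied by the ratio of calibrated washout rates and is recorded
#' in the truth table. With `render = "images"` full noisy PSF-blurred
#' NIfTI-ready volumes are produced; with `render = "tac"` only regional
#' curves (with region-mean-level noise) are kept, which is much faster.
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed; subject-level RNG streams are derived
#'   from it, so truth tables are reproducible and stable.
#' @param render `"tac"` (regional curves only) or `"images"` (full
#'   volumes).
#' @param out_dir if non-NULL (with `render = "images"`), writes per-subject
#'   NIfTI files and `truth.csv` there.
#' @return A `cohort`: list with `subjects` (per-subject lists), `truth`
#'   (data frame), `atlas`, `schedule`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            render = c("tac", "images"), out_dir = NULL) {
  render <- match.arg(render)
  validate_cohort_config(config)
  sched <- parse_frame_spec(config$frame_spec)
  atlas <- build_phantom(default_phantom_spec(config$grid_shape,
                                              config$voxel_size_mm,
                                              config$n_cortex_sectors))
  n <- config$n_unblocked + config$n_blocked
  blocked <- rep(c(FALSE, TRUE), c(config$n_unblocked, config$n_blocked))
  cp_template <- input_function(total_duration(sched) + 1,
                                dt_s = config$cp_dt_s, peak_value = 1)
  subjects <- vector("list", n)
  truth <- vector("list", n)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  for (i in seq_len(n)) {
    set.seed((seed %% 100000L) * 10007L + i)
    subjects[[i]] <- simulate_subject(i, blocked[i], config, atlas, sched,
                                      cp_template, render, out_dir)
    truth[[i]] <- subjects[[i]]$truth
  }
  truth <- do.call(rbind, truth)
  if (!is.null(out_dir))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  structure(list(subjects = subjects, truth = truth, atlas = atlas,
                 schedule = sched, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d blocked), %d regions, %d frames\n",
              nrow(x$truth), sum(x$truth$blocked),
              nrow(x$atlas$regions), nrow(x$schedule)))
  invisible(x)
}

simulate_subject <- function(idx, blocked, config, atlas, sched,
                             cp_template, render, out_dir) {
  pk <- if (blocked) config$blocked_peak else config$unblocked_peak
  peak_suv <- rnorm_trunc(1, pk$suv_mean, pk$suv_sd, lo = 1.5)
  # peak times truncated at ~2.25 SD: the 1TC peak-time inversion is steep
  # near the bolus, so extreme draws would imply implausible washout rates
  peak_time <- if (blocked)
    rnorm_trunc(1, pk$time_mean, pk$time_sd, lo = 1.5, hi = 4.5)
  else rnorm_trunc(1, pk$time_mean, pk$time_sd, lo = 2.0, hi = 7.0)
  dose <- rnorm_trunc(1, config$dose_MBq$mean, config$dose_MBq$sd, lo = 50)
  fdg_dose <- rnorm_trunc(1, config$fdg_dose_MBq$mean,
                          config$fdg_dose_MBq$sd, lo = 50)
  weight <- rnorm_trunc(1, config$weight_kg$mean, config$weight_kg$sd,
                        lo = 40, hi = 140)
  # subject plasma curve in SUV-equivalent units
  cp <- cp_template
  cp$cp <- cp$cp * 30 * exp(stats::rnorm(1, 0, 0.05))
  k2_eff <- solve_k2_for_peak(peak_time, cp)
  if (blocked) {
    # a blocked subject's pre-blockade washout follows the unblocked
    # distribution; the implied occupancy (ratio of calibrated washout
    # rates) is rejection-sampled into the plausible blockade range
    # (regional blocking of roughly 40-75% under SV2A medication)
    for (i in 1:100) {
      baseline_time <- rnorm_trunc(1, config$unblocked_peak$time_mean,
                                   config$unblocked_peak$time_sd,
                                   lo = max(2.5, peak_time + 0.3), hi = 6.5)
      k2_base <- solve_k2_for_peak(baseline_time, cp)
      occupancy <- 1 - k2_base / k2_eff
      if (occupancy >= 0.30 && occupancy <= 0.85) break
    }
    occupancy <- min(max(occupancy, 0.30), 0.85)
    k2_eff <- k2_base / (1 - occupancy)
  } else {
    k2_base <- k2_eff
    occupancy <- 0
  }
  K1_cortex <- peak_suv / max(ct_fine(1, k2_eff, cp))

  reg <- atlas$regions
  regional <- config$regional
  tindex <- match(reg$tissue, regional$tissue)
  if (anyNA(tindex))
    stop("atlas tissue missing from the regional multiplier table")
  nlab <- nrow(reg)
  # per-subject regional variability is drawn once per left/right region
  # pair: anatomy is mirror-symmetric, so only lesions (and noise) break
  # hemispheric symmetry
  pair_id <- sub("_(left|right)$", "", reg$name)
  pairs <- unique(pair_id)
  dm <- stats::setNames(exp(stats::rnorm(length(pairs), 0,
                                         config$region_cv)), pairs)
  bm <- stats::setNames(exp(stats::rnorm(length(pairs), 0,
                                         config$region_cv)), pairs)
  delivery_mult <- unname(dm[pair_id])
  binding_mult <- unname(bm[pair_id])

  params <- vector("list", nlab)
  names(params) <- as.character(reg$label)
  for (r in seq_len(nlab)) {
    tis <- reg$tissue[r]
    if (tis == "blood") next  # blood pool carries the input function
    ri <- tindex[r]
    K1_r <- K1_cortex * regional$K1_mult[ri] * delivery_mult[r]
    VT_r <- (K1_cortex / k2_base) * regional$VT_mult[ri] * binding_mult[r]
    occ_r <- occupancy * regional$specific_frac[ri]
    params[[r]] <- kinetic_params(K1_r, K1_r / VT_r, occ_r)
  }

  # noise-free regional TACs in SUV units; the blood pool carries Cp itself
  tacs <- vector("list", nlab)
  names(tacs) <- as.character(reg$label)
  for (r in seq_len(nlab)) {
    tacs[[r]] <- if (reg$tissue[r] == "blood")
      new_tac(sched, frame_average(cp$cp, cp$time_s, sched))
    else simulate_tac(params[[r]], cp, sched)
  }

  # FDG pattern: tracks regional delivery (metabolism-like), independent of
  # binding; subject-level scale follows cortical delivery
  fdg_scale <- (K1_cortex / 0.12) * exp(stats::rnorm(1, 0, 0.10))
  fm <- stats::setNames(exp(stats::rnorm(length(pairs), 0,
                                         config$region_cv / 2)), pairs)
  fdg_uptake <- regional$fdg_uptake[tindex] * delivery_mult *
    unname(fm[pair_id]) * fdg_scale
  names(fdg_uptake) <- as.character(reg$label)

  les <- config$lesion
  lesion_late <- lesion_early <- lesion_fdg <- NULL
  severity <- perfusion <- fdg_severity <- NA_real_
  side <- NA_character_
  if (!is.null(les)) {
    side <- if (stats::runif(1) < les$p_left) "left" else "right"
    severity <- rnorm_trunc(1, les$severity_mean, les$severity_sd,
                            lo = 0.05, hi = 0.9)
    perfusion <- rnorm_trunc(1, les$perfusion_mean, les$perfusion_sd,
                             lo = 0.02, hi = 0.9)
    fdg_severity <- rnorm_trunc(1, les$fdg_severity_mean,
                                les$fdg_severity_sd, lo = 0.05, hi = 0.9)
    sd_late <- if (is.null(les$radius_late_sd_mm)) 0 else les$radius_late_sd_mm
    sd_early <- if (is.null(les$radius_early_sd_mm)) 0 else les$radius_early_sd_mm
    r_late <- rnorm_trunc(1, les$radius_late_mm, sd_late, lo = 5)
    r_early <- rnorm_trunc(1, les$radius_early_mm, sd_early,
                           lo = r_late + 2)
    lesion_late <- lesion_spec(les$center_region, side, r_late,
                               severity, perfusion)
    lesion_early <- lesion_spec(les$center_region, side, r_early, 0,
                                perfusion)
    lesion_fdg <- lesion_spec(les$center_region, side, r_early,
                              fdg_severity, 0)
  }

  subj <- list(id = sprintf("sub%02d", idx), blocked = blocked, cp = cp,
               params = params, tacs = tacs, fdg_uptake = fdg_uptake,
               lesions = list(late = lesion_late, early = lesion_early,
                              fdg = lesion_fdg),
               dose_MBq = dose, fdg_dose_MBq = fdg_dose,
               weight_kg = weight)

  vox_mL <- prod(atlas$voxel_size_mm) / 1000
  if (render == "images") {
    img <- render_subject_images(subj, config, atlas, sched)
    subj$dynamic <- img$dynamic
    subj$fdg <- img$fdg
    if (!is.null(out_dir)) {
      write_pet_nifti(img$dynamic,
                      file.path(out_dir, paste0(subj$id, "_dyn.nii.gz")))
      write_pet_nifti(img$fdg,
                      file.path(out_dir, paste0(subj$id, "_fdg.nii.gz")))
    }
  } else {
    subj$tacs_noisy <- add_tac_noise(subj$tacs, atlas, sched,
                                     config$noise_scale)
  }

  n_late <- if (is.null(lesion_late)) 0L else
    sum(lesion_voxels(atlas, lesion_late))
  n_early <- if (is.null(lesion_early)) 0L else
    sum(lesion_voxels(atlas, lesion_early))
  subj$truth <- data.frame(
    subject = subj$id, blocked = blocked, occupancy = occupancy,
    dose_MBq = dose, fdg_dose_MBq = fdg_dose, weight_kg = weight,
    peak_suv = peak_suv, peak_time_min = peak_time,
    K1_cortex = K1_cortex, k2_cortex = k2_base,
    lesion_side = side, severity_frac = severity,
    perfusion_frac = perfusion, fdg_severity_frac = fdg_severity,
    radius_late_mm = if (is.null(lesion_late)) NA_real_ else
      lesion_late$radius_mm,
    radius_early_mm = if (is.null(lesion_early)) NA_real_ else
      lesion_early$radius_mm,
    lesion_volume_late_mL = n_late * vox_mL,
    lesion_volume_early_mL = n_early * vox_mL
  )
  subj
}

# region-mean-level noise for TAC-only cohorts: SD of the mean over a
# region with nvox voxels is the voxel SD / sqrt(nvox)
add_tac_noise <- function(tacs, atlas, sched, noise_scale) {
  if (noise_scale <= 0) return(tacs)
  counts <- tabulate(atlas$labels[atlas$labels > 0L],
                     nbins = max(atlas$regions$label))
  out <- tacs
  for (nm in names(tacs)) {
    nv <- counts[as.integer(nm)]
    sd <- noise_scale * sqrt(pmax(tacs[[nm]]$value, 0.01) /
                               sched$duration_s) / sqrt(nv)
    out[[nm]]$value <- tacs[[nm]]$value + stats::rnorm(nrow(sched), 0, sd)
  }
  out
}

# Lesioned variant of a regional TAC. The perfusion deficit scales K1 and
# the effective k2 together (delivery reduced, binding potential
# preserved). The synaptic deficit then inflates the washout rate until
# the late-window signal is reduced by exactly severity_frac relative to
# the unlesioned curve, realising the severity as the late-phase binding
# reduction the asymmetry analysis measures.
lesion_tac <- function(p0, pf, sev, cp, sched, window = c(1800, 3600)) {
  sim <- function(K1, k2) new_tac(sched, frame_average(ct_fine(K1, k2, cp),
                                                       cp$time_s, sched))
  K1p <- p0$K1 * (1 - pf)
  k2p <- p0$k2_eff * (1 - pf)
  if (sev <= 0) return(sim(K1p, k2p))
  base <- sim(p0$K1, p0$k2_eff)
  target <- (1 - sev) * tac_window_mean(base, window[1], window[2])
  f <- function(m) tac_window_mean(sim(K1p, k2p * m), window[1],
                                   window[2]) - target
  m <- stats::uniroot(f, c(1, 200), extendInt = "downX", tol = 1e-6)$root
  sim(K1p, k2p * m)
}

# Render the dynamic + static volumes for one subject, applying the lesion
# by splitting affected labels: the broad perfusion deficit reduces
# delivery over the metabolic extent, the synaptic core additionally
# carries the calibrated late-phase binding reduction. SUV-equivalent TACs
# are converted to kBq/mL with the subject's dose/weight.
render_subject_images <- function(subj, config, atlas, sched) {
  labarr <- atlas$labels
  tacs <- subj$tacs
  reg <- atlas$regions
  if (!is.null(subj$lesions$late)) {
    outer <- lesion_voxels(atlas, subj$lesions$early)
    inner <- lesion_voxels(atlas, subj$lesions$late)
    pf <- subj$lesions$early$perfusion_frac
    sev <- subj$lesions$late$severity_frac
    next_label <- max(reg$label) + 1L
    for (zone in list(list(mask = outer & !inner, pf = pf, sev = 0),
                      list(mask = inner, pf = pf, sev = sev))) {
      for (lb in setdiff(unique(labarr[zone$mask]), 0L)) {
        if (reg$tissue[match(lb, reg$label)] == "blood") next
        p0 <- subj$params[[as.character(lb)]]
        tacs[[as.character(next_label)]] <-
          lesion_tac(p0, zone$pf, zone$sev, subj$cp, sched)
        labarr[zone$mask & atlas$labels == lb] <- next_label
        next_label <- next_label + 1L
      }
    }
  }
  aug_regions <- data.frame(label = sort(unique(as.vector(labarr[labarr > 0L]))))
  aug_regions$name <- paste0("r", aug_regions$label)
  aug_regions$side <- "midline"
  aug_regions$tissue <- "any"
  aug <- label_volume(labarr, atlas$voxel_size_mm, aug_regions)
  # kBq/mL = SUV * dose[kBq]/weight[g]
  suv2act <- (subj$dose_MBq * 1000) / (subj$weight_kg * 1000)
  tacs_act <- lapply(tacs, function(tc) { tc$value <- tc$value * suv2act; tc })
  dyn <- render_dynamic_image(aug, tacs_act, sched,
                              psf_fwhm_mm = config$psf_fwhm_mm,
                              noise_scale = config$noise_scale,
                              seed = sample.int(.Machine$integer.max, 1),
                              injected_dose_MBq = subj$dose_MBq,
                              body_weight_kg = subj$weight_kg)
  fdg_suv2act <- (subj$fdg_dose_MBq * 1000) / (subj$weight_kg * 1000)
  fdg <- render_static_fdg(atlas, subj$fdg_uptake * fdg_suv2act,
                           lesion = subj$lesions$fdg,
                           psf_fwhm_mm = config$psf_fwhm_mm,
                           noise_scale = config$noise_scale,
                           seed = sample.int(.Machine$integer.max, 1),
                           injected_dose_MBq = subj$fdg_dose_MBq,
                           body_weight_kg = subj$weight_kg)
  list(dynamic = dyn, fdg = fdg)
}
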
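#' Pipeline configuration
#'
#' Bundles the cohort generator settings with the analysis parameters:
#' early/late windows (defaults 0-600 s and 1800-3600 s), reference regions
#' per phase (early: cerebellum; late: centrum semiovale; alternates pons
#' and global mean), smoothing kernel, asymmetry threshold, retention
#' fraction and the master seed. Round-trips through YAML unchanged.
#'
#' @param cohort a [cohort_config()] (or a plain list of its fields).
#' @param windows named list of `c(t0_s, t1_s)`.
#' @param reference_early,reference_late reference tissue per phase.
#' @param smoothing_fwhm_mm asymmetry smoothing kernel (mm).
#' @param asymmetry_threshold_pct suprathreshold cut (percent).
#' @param keep_fraction most-affected retention fraction.
#' @param t_star_min Logan fit start (minutes).
#' @param k2_ref reference efflux rate for reference-Logan runs (1/min).
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            windows = list(early = c(0, 600),
                                           late = c(1800, 3600)),
                            reference_early = "cerebellum",
                            reference_late = "centrum_semiovale",
                            smoothing_fwhm_mm = 8,
                            asymmetry_threshold_pct = 8,
                            keep_fraction = 0.90,
                            t_star_min = 15,
                            k2_ref = 0.05,
                            seed = 1L) {
  if (!inherits(cohort, "cohort_config"))
    cohort <- do.call(cohort_config, cohort)
  cfg <- structure(list(cohort = cohort, windows = windows,
                        reference_early = reference_early,
                        reference_late = reference_late,
                        smoothing_fwhm_mm = smoothing_fwhm_mm,
                        asymmetry_threshold_pct = asymmetry_threshold_pct,
                        keep_fraction = keep_fraction,
                        t_star_min = t_star_min, k2_ref = k2_ref,
                        seed = as.integer(seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  sched <- parse_frame_spec(cfg$cohort$frame_spec)
  for (w in names(cfg$windows)) {
    win <- cfg$windows[[w]]
    if (length(win) != 2L || win[1] >= win[2])
      stop(sprintf("window '%s' must be c(t0, t1) with t0 < t1", w))
    if (win[1] < sched$start_s[1] - 1e-9 ||
        win[2] > sched$end_s[nrow(sched)] + 1e-9)
      stop(sprintf("window '%s' [%g, %g] s lies outside the scan (0-%g s)",
                   w, win[1], win[2], total_duration(sched)))
    if (length(frames_in_window(sched, win[1], win[2])) == 0L)
      stop(sprintf("window '%s' contains no full frame", w))
  }
  stopifnot(cfg$smoothing_fwhm_mm >= 0, cfg$asymmetry_threshold_pct >= 0,
            cfg$keep_fraction > 0, cfg$keep_fraction <= 1, cfg$k2_ref > 0)
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$cohort <- do.call(cohort_config, c(
    raw$cohort[setdiff(names(raw$cohort), "regional")],
    if (!is.null(raw$cohort$regional))
      list(regional = as.data.frame(raw$cohort$regional))))
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$regional <- as.list(x$cohort$regional)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Run the full simulate-to-report pipeline
#'
#' Generates the cohort (full image rendering), writes per-subject NIfTI
#' volumes and the truth table, extracts TACs, runs the blocked/unblocked
#' group comparison, the framewise cross-tracer correlation with window
#' selection, per-subject asymmetry mapping for the three modalities with
#' lesion metrics, Logan kinetics from the image-derived input function,
#' and the cross-modality report. Every artifact is listed in a manifest
#' with its MD5 checksum; a rerun with the same config and seed is
#' bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param verbose print stage progress to stderr.
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         verbose = TRUE) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "simulate"
  res <- tryCatch({
    say("[simulate] generating cohort (seed %d)", config$seed)
    cohort <- generate_cohort(config$cohort, seed = config$seed,
                              render = "images",
                              out_dir = file.path(out_dir, "cohort"))
    atlas <- cohort$atlas
    write_pet_nifti(atlas, file.path(out_dir, "cohort", "atlas.nii.gz"))
    utils::write.csv(atlas$regions,
                     file.path(out_dir, "cohort", "regions.csv"),
                     row.names = FALSE)

    stage <- "tac"
    say("[tac] extracting regional curves")
    tacs <- cohort_tac_table(cohort)
    utils::write.csv(tacs, file.path(out_dir, "tacs.csv"),
                     row.names = FALSE)
    tissue_tacs <- collapse_tissue(tacs, atlas)
    blocked <- stats::setNames(cohort$truth$blocked, cohort$truth$subject)
    cmp <- if (sum(blocked) >= 2 && sum(!blocked) >= 2)
      compare_groups(tissue_tacs[tissue_tacs$region != "blood", ], blocked,
                     windows = config$windows) else NULL
    if (!is.null(cmp))
      utils::write.csv(cmp, file.path(out_dir, "group_comparison.csv"),
                       row.names = FALSE)

    stage <- "correlate"
    say("[correlate] framewise cross-tracer correlation")
    fw <- pipeline_framewise(cohort, tissue_tacs, config)
    utils::write.csv(fw$curves, file.path(out_dir, "framewise_correlation.csv"),
                     row.names = FALSE)
    utils::write.csv(fw$windows, file.path(out_dir, "selected_windows.csv"),
                     row.names = FALSE)

    stage <- "asymmetry"
    say("[asymmetry] lesion mapping per subject")
    met <- pipeline_asymmetry(cohort, config, out_dir)
    utils::write.csv(met, file.path(out_dir, "lesion_metrics_raw.csv"),
                     row.names = FALSE)

    stage <- "kinetics"
    say("[kinetics] Logan graphical analysis")
    kin <- pipeline_kinetics(cohort, config)
    utils::write.csv(kin, file.path(out_dir, "kinetics.csv"),
                     row.names = FALSE)

    stage <- "report"
    say("[report] cross-modality comparison")
    report <- fig_report(met)
    write_report(report, file.path(out_dir, "report"))
    report
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  info <- list(package_version = as.character(utils::packageVersion("dualphasepet")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               seed = config$seed)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  info$config_md5 <- unname(tools::md5sum(cfg_path))
  yaml::write_yaml(info, file.path(out_dir, "run_info.yaml"))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE,
                                   full.names = TRUE),
                        file.path(out_dir, "manifest.csv")))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# framewise correlation (cortex, SUV and early-reference SUVR) against the
# static tracer
pipeline_framewise <- function(cohort, tissue_tacs, config) {
  atlas <- cohort$atlas
  sched <- cohort$schedule
  fdg_reg <- pipeline_fdg_regional(cohort)
  ctx <- tissue_tacs[tissue_tacs$region == "cortex", ]
  ref <- tissue_tacs[tissue_tacs$region == config$reference_early, ]
  fdg_ctx <- fdg_reg["cortex", ]
  fdg_ref <- fdg_reg[config$reference_early, ]
  cur_suv <- framewise_correlation(ctx, fdg_ctx, scaling = "SUV")
  ctx_r <- ctx
  ctx_r$value <- ctx$value / ref$value[match(
    paste(ctx$subject, ctx$frame), paste(ref$subject, ref$frame))]
  cur_suvr <- framewise_correlation(ctx_r, fdg_ctx / fdg_ref,
                                    scaling = paste0("SUVR:",
                                                     config$reference_early))
  curves <- rbind(cur_suv, cur_suvr)
  wins <- lapply(list(cur_suv, cur_suvr), function(cu) {
    w <- select_windows(cu, sched)
    if (nrow(w)) cbind(scaling = cu$scaling[1], w) else NULL
  })
  wins <- do.call(rbind, wins)
  if (is.null(wins))
    wins <- data.frame(scaling = character(0), t_start_s = numeric(0),
                       t_end_s = numeric(0), first_frame = integer(0),
                       last_frame = integer(0))
  list(curves = curves, windows = wins)
}

# per-subject regional FDG means (SUV) as a matrix tissue x subject
pipeline_fdg_regional <- function(cohort) {
  atlas <- cohort$atlas
  tissues <- unique(atlas$regions$tissue)
  vals <- vapply(cohort$subjects, function(s) {
    img <- if (!is.null(s$fdg)) suv(s$fdg)$voxels else NULL
    vapply(tissues, function(tt) {
      labs <- atlas$regions$label[atlas$regions$tissue == tt]
      if (is.null(img)) {
        mean(s$fdg_uptake[as.character(labs)])
      } else mean(img[atlas$labels %in% labs])
    }, numeric(1))
  }, numeric(length(tissues)))
  rownames(vals) <- tissues
  colnames(vals) <- vapply(cohort$subjects, `[[`, character(1), "id")
  vals
}

# asymmetry maps + lesion metrics for fdg / early / late per subject
pipeline_asymmetry <- function(cohort, config, out_dir = NULL) {
  stopifnot(!is.null(cohort$subjects[[1]]$dynamic))
  map_dir <- if (!is.null(out_dir)) file.path(out_dir, "asymmetry") else NULL
  if (!is.null(map_dir)) dir.create(map_dir, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$subjects) {
    side <- cohort$truth$lesion_side[cohort$truth$subject == s$id]
    if (is.na(side)) next
    imgs <- list(
      fdg = s$fdg,
      early = window_average(s$dynamic, config$windows$early[1],
                             config$windows$early[2]),
      late = window_average(s$dynamic, config$windows$late[1],
                            config$windows$late[2]))
    for (m in names(imgs)) {
      map <- percent_difference_map(imgs[[m]], cohort$atlas, side,
                                    config$smoothing_fwhm_mm)
      msk <- lesion_mask(map, config$asymmetry_threshold_pct,
                         config$keep_fraction)
      met <- lesion_metrics(map, msk)
      if (!is.null(map_dir))
        write_asymmetry_nifti(map, file.path(map_dir,
                                             sprintf("%s_%s_delta.nii.gz",
                                                     s$id, m)))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$id, modality = m, side = side,
        severity_pct = met$severity_pct, volume_mL = met$volume_mL,
        n_voxels = met$n_voxels)
    }
  }
  do.call(rbind, rows)
}

# Logan kinetics from the image-derived input function, per subject and
# tissue, referenced to the late-phase reference region
pipeline_kinetics <- function(cohort, config) {
  atlas <- cohort$atlas
  blood <- atlas$labels %in%
    atlas$regions$label[atlas$regions$tissue == "blood"]
  rows <- list()
  for (s in cohort$subjects) {
    tacs <- list()
    for (tt in setdiff(unique(atlas$regions$tissue), "blood")) {
      labs <- atlas$regions$label[atlas$regions$tissue == tt]
      tacs[[tt]] <- if (!is.null(s$dynamic))
        extract_tac(s$dynamic, atlas$labels %in% labs)
      else {
        tc <- s$tacs[[as.character(labs[1])]]
        if (length(labs) > 1L)
          tc$value <- rowMeans(vapply(as.character(labs), function(lb)
            s$tacs[[lb]]$value, numeric(nrow(tc))))
        tc
      }
    }
    idif <- if (!is.null(s$dynamic)) idif_extract(s$dynamic, blood) else s$cp
    out <- kinetic_outcomes(tacs, idif, config$reference_late,
                            config$t_star_min, config$k2_ref)
    out$subject <- s$id
    rows[[length(rows) + 1L]] <- out
  }
  do.call(rbind, rows)
}
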